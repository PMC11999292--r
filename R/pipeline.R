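#' Crop the disc region of a fundus image for classification
#'
#' Takes a square crop centered on the disc-mask centroid with side twice
#' the mask's largest bounding-box dimension (clamped to the image), then
#' resizes it to `target_side` with bilinear interpolation -- the
#' "segmented output" handed to the capsule network. An empty mask falls
#' back to a centered crop of half the image side, with a warning.
#'
#' @param image `H x W x C` array in `[0, 1]`.
#' @param disc_mask Logical matrix (predicted disc).
#' @param target_side Output side in pixels.
#' @return `target_side x target_side x C` array.
#' @export
crop_disc_region <- function(image, disc_mask, target_side = 64) {
  H <- dim(image)[1]; W <- dim(image)[2]
  w <- which(disc_mask, arr.ind = TRUE)
  if (nrow(w) == 0) {
    warning("empty disc mask: falling back to a center crop")
    side <- round(min(H, W) / 2)
    cr <- round(H / 2); cc <- round(W / 2)
  } else {
    cr <- mean(w[, 1]); cc <- mean(w[, 2])
    bb <- max(diff(range(w[, 1])), diff(range(w[, 2]))) + 1
    side <- min(2 * bb, min(H, W))
  }
  side <- max(side, 8)
  r0 <- round(cr - side / 2); c0 <- round(cc - side / 2)
  r0 <- min(max(r0, 1), H - side + 1)
  c0 <- min(max(c0, 1), W - side + 1)
  crop <- image[r0:(r0 + side - 1), c0:(c0 + side - 1), , drop = FALSE]
  out <- EBImage::resize(crop, w = target_side, h = target_side)
  array(as.numeric(out), dim = c(target_side, target_side, dim(image)[3]))
}

#' Confusion counts of predicted vs. true labels
#'
#' Glaucoma is the positive class throughout the package.
#'
#' @param truth,predicted Character vectors of `"glaucoma"` / `"normal"`.
#' @return A list with integers `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  list(tp = sum(truth == "glaucoma" & predicted == "glaucoma"),
       fp = sum(truth == "normal" & predicted == "glaucoma"),
       tn = sum(truth == "normal" & predicted == "normal"),
       fn = sum(truth == "glaucoma" & predicted == "normal"))
}

#' Screening metrics from confusion counts
#'
#' Accuracy, precision, recall, sensitivity (identically recall) and
#' specificity, all as percentages. A ratio with a zero denominator is
#' reported as `NA` with a warning, never as 0.
#'
#' @param counts A list/vector with `tp`, `fp`, `tn`, `fn`
#'   (glaucoma = positive).
#' @return A one-row tibble: `accuracy`, `precision`, `recall`,
#'   `sensitivity`, `specificity` (percent).
#' @export
#' @examples
#' compute_metrics(list(tp = 45, fn = 5, tn = 40, fp = 10))
compute_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  stopifnot(!is.null(tp), !is.null(fp), !is.null(tn), !is.null(fn),
            tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  total <- tp + fp + tn + fn
  if (total == 0) stop("no evaluated samples (total = 0)")
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined: zero denominator")
      return(NA_real_)
    }
    num / den
  }
  recall <- 100 * ratio(tp, tp + fn, "recall/sensitivity")
  tibble::tibble(
    accuracy = 100 * (tp + tn) / total,
    precision = 100 * ratio(tp, tp + fp, "precision"),
    recall = recall,
    sensitivity = recall,
    specificity = 100 * ratio(tn, tn + fp, "specificity"))
}

#' Default pipeline configuration
#'
#' Mirrors the reference training setup (Adam, learning rate 1e-4, batch
#' size 32, up to 100 epochs with early stopping, 80:20 split). The shipped
#' example configuration (`inst/extdata/example_config.yaml`) overrides
#' these with desk-scale values that train in minutes on one CPU.
#'
#' @return A nested list understood by [run_pipeline()].
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    data = list(image_side = 128L, n_per_class = 40L, crop_side = 64L),
    gwo = list(enabled = FALSE, n_wolves = 5L, max_iters = 5L,
               budget_epochs = 5L, variant = "standard"),
    segmenter = list(depth = 2L, base_filters = 16L, dropout_rate = 0.1,
                     learning_rate = 1e-4, binarize_threshold = 0.5,
                     epochs = 100L, patience = 10L),
    capsnet = list(conv_filters = 256L, primary_caps_types = 32L,
                   routing_iters = 3L, epochs = 100L, batch_size = 32L,
                   learning_rate = 1e-4, patience = 10L),
    eval = list(train_fraction = 0.8))
}

#' Validate a pipeline configuration
#'
#' @param config A nested list (see [default_pipeline_config()]); missing
#'   keys are filled from the defaults.
#' @return The completed configuration, invisibly on success; errors list
#'   every offending key.
#' @export
validate_pipeline_config <- function(config) {
  def <- default_pipeline_config()
  merged <- utils::modifyList(def, config)
  extra <- setdiff(names(config), names(def))
  bad <- character()
  if (length(extra)) bad <- c(bad, paste0("unknown key: ", extra))
  chk <- function(cond, key) if (!isTRUE(cond)) bad <<- c(bad, key)
  chk(merged$eval$train_fraction > 0 && merged$eval$train_fraction < 1,
      "eval.train_fraction must be in (0, 1)")
  chk(merged$data$n_per_class >= 2, "data.n_per_class must be >= 2")
  chk(merged$data$image_side %% 2^merged$segmenter$depth == 0,
      "data.image_side must be divisible by 2^segmenter.depth")
  chk(merged$segmenter$learning_rate > 0,
      "segmenter.learning_rate must be positive")
  chk(merged$capsnet$learning_rate > 0,
      "capsnet.learning_rate must be positive")
  chk(merged$gwo$n_wolves >= 3, "gwo.n_wolves must be >= 3")
  if (length(bad))
    stop("invalid pipeline config:\n  ", paste(bad, collapse = "\n  "))
  invisible(merged)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with any subset of the keys of
#'   [default_pipeline_config()].
#' @return The validated, completed configuration.
#' @export
read_pipeline_config <- function(path) {
  validate_pipeline_config(yaml::read_yaml(path))
}

#' Run the full screening pipeline
#'
#' Orchestrates generate -> (optionally GWO-tune) -> train segmenter ->
#' segment -> crop disc regions -> train capsule classifier -> evaluate,
#' with per-stage seeds derived from the configured seed. Writes predicted
#' masks and crops (PNG), `metrics.csv`, `predictions.csv`, the GWO trace
#' (if tuning ran) and a run log with all resolved parameters under
#' `out_dir`.
#'
#' @param config A configuration list, or a path to a YAML file.
#' @param out_dir Output directory for artifacts (`NULL` skips all disk
#'   output).
#' @param dry_run If `TRUE`, print the stage plan and execute nothing.
#' @param verbose Print one line per stage transition.
#' @return An object of class `screening_result`: `per_image` tibble,
#'   `counts`, `metrics` (classification, percent), `seg_dice` (test-set
#'   mean disc/cup Dice), `tuning` (or `NULL`), fitted models, and the
#'   resolved `config`.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir = NULL, dry_run = FALSE, verbose = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- validate_pipeline_config(config)
  stages <- c("generate", if (cfg$gwo$enabled) "tune-seg", "train-seg",
              "segment+crop", "train-caps", "evaluate")
  if (dry_run) {
    cat("pipeline stage plan:\n", paste0("  ", seq_along(stages), ". ",
                                         stages, collapse = "\n"), "\n",
        sep = "")
    return(invisible(stages))
  }
  logf <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    logf <- file.path(out_dir, "run.log")
    cat("resolved config:\n", yaml::as.yaml(cfg), file = logf)
  }
  say <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    if (!is.null(logf)) cat(line, "\n", file = logf, append = TRUE)
    if (verbose) message(line)
  }
  seed <- cfg$seed

  say("stage generate: seed ", seed)
  ds <- generate_fundus_dataset(
    fundus_params(image_side = cfg$data$image_side, seed = seed),
    cfg$data$n_per_class)
  sp <- split_dataset(ds$manifest, cfg$eval$train_fraction,
                      stratify = TRUE, seed = seed + 1L)
  idx_of <- stats::setNames(seq_len(nrow(ds$manifest)), ds$manifest$id)
  tr_i <- idx_of[sp$train$id]; te_i <- idx_of[sp$test$id]
  imgs <- lapply(ds$samples, `[[`, "image")
  masks <- lapply(ds$samples, function(s)
    array(c(s$disc_mask, s$cup_mask),
          dim = c(dim(s$disc_mask), 2)))
  labels <- ds$manifest$label

  tuning <- NULL
  if (cfg$gwo$enabled) {
    say("stage tune-seg: ", cfg$gwo$n_wolves, " wolves, ",
        cfg$gwo$max_iters, " iterations, seed ", seed + 2L)
    gcfg <- gwo_config(cfg$gwo$n_wolves, 4L, cfg$gwo$max_iters,
                       seg_search_space()$lower, seg_search_space()$upper,
                       variant = cfg$gwo$variant, seed = seed + 2L)
    tuning <- gwo_tune_segmenter(imgs[tr_i], masks[tr_i],
                                 gwo_config = gcfg,
                                 budget_epochs = cfg$gwo$budget_epochs,
                                 depth = cfg$segmenter$depth,
                                 eval_seed = seed + 3L)
    seg_cfg <- tuning$best_config
  } else {
    seg_cfg <- seg_config(depth = cfg$segmenter$depth,
                          base_filters = cfg$segmenter$base_filters,
                          dropout_rate = cfg$segmenter$dropout_rate,
                          learning_rate = cfg$segmenter$learning_rate,
                          binarize_threshold = cfg$segmenter$binarize_threshold)
  }

  say("stage train-seg: ", cfg$segmenter$epochs, " epochs, seed ", seed + 4L)
  seg_model <- build_segmenter(seg_cfg, in_channels = 3, seed = seed + 4L)
  seg_fit <- train_segmenter(seg_model, imgs[tr_i], masks[tr_i],
                             epochs = cfg$segmenter$epochs,
                             seed = seed + 5L,
                             patience = cfg$segmenter$patience)
  seg_model <- seg_fit$model

  say("stage segment+crop")
  segs <- lapply(imgs, function(im) segment(seg_model, im))
  crops <- lapply(seq_along(imgs), function(i)
    crop_disc_region(imgs[[i]], segs[[i]]$disc, cfg$data$crop_side))
  cdr_est <- vapply(segs, function(s) {
    v <- mask_cdr(s$disc, s$cup)
    if (is.na(v)) 0 else v
  }, 0.0)

  say("stage train-caps: ", cfg$capsnet$epochs, " epochs, seed ", seed + 6L)
  spec <- capsnet_spec(input_side = cfg$data$crop_side,
                       conv_filters = cfg$capsnet$conv_filters,
                       primary_caps_types = cfg$capsnet$primary_caps_types,
                       routing_iters = cfg$capsnet$routing_iters)
  caps_model <- build_capsnet(spec, seed = seed + 6L)
  caps_fit <- train_capsnet(caps_model, crops[tr_i], labels[tr_i],
                            epochs = cfg$capsnet$epochs,
                            batch_size = cfg$capsnet$batch_size,
                            learning_rate = cfg$capsnet$learning_rate,
                            seed = seed + 7L,
                            patience = cfg$capsnet$patience)
  caps_model <- caps_fit$model

  say("stage evaluate: ", length(te_i), " test images")
  preds <- predict_capsnet(caps_model, crops[te_i],
                           image_id = ds$manifest$id[te_i], tta = TRUE)
  counts <- confusion_counts(labels[te_i], preds$predicted_label)
  metrics <- compute_metrics(counts)
  dice_disc <- vapply(te_i, function(i)
    dice(segs[[i]]$disc, masks[[i]][, , 1] > 0.5), 0.0)
  dice_cup <- vapply(te_i, function(i)
    dice(segs[[i]]$cup, masks[[i]][, , 2] > 0.5), 0.0)

  per_image <- tibble::tibble(
    id = ds$manifest$id,
    split = ifelse(seq_along(imgs) %in% tr_i, "train", "test"),
    label = labels,
    cdr_true = ds$manifest$cdr,
    cdr_estimate = cdr_est) |>
    dplyr::left_join(preds, by = c(id = "image_id"))

  if (!is.null(out_dir)) {
    mdir <- file.path(out_dir, "masks")
    cdir <- file.path(out_dir, "crops")
    dir.create(mdir, showWarnings = FALSE)
    dir.create(cdir, showWarnings = FALSE)
    for (i in seq_along(imgs)) {
      id <- ds$manifest$id[i]
      png::writePNG(segs[[i]]$disc * 1.0,
                    file.path(mdir, paste0(id, "_disc.png")))
      png::writePNG(segs[[i]]$cup * 1.0,
                    file.path(mdir, paste0(id, "_cup.png")))
      png::writePNG(crops[[i]], file.path(cdir, paste0(id, ".png")))
    }
    utils::write.csv(preds, file.path(out_dir, "predictions.csv"),
                     row.names = FALSE)
    mrows <- dplyr::bind_rows(
      dplyr::mutate(tidyr::pivot_longer(metrics, dplyr::everything(),
                                        names_to = "metric"),
                    block = "classification"),
      tibble::tibble(metric = c("dice_disc", "dice_cup"),
                     value = c(mean(dice_disc), mean(dice_cup)),
                     block = "segmentation"))
    utils::write.csv(mrows, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    if (!is.null(tuning))
      write_gwo_trace(tuning$result, file.path(out_dir, "gwo_trace.csv"))
    say("artifacts written to ", out_dir)
  }

  structure(
    list(per_image = per_image, counts = counts, metrics = metrics,
         seg_dice = c(disc = mean(dice_disc), cup = mean(dice_cup)),
         tuning = tuning, seg_fit = seg_fit, caps_fit = caps_fit,
         config = cfg),
    class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat("<screening_result> ", sum(x$per_image$split == "test"),
      " test images\n  accuracy ", round(x$metrics$accuracy, 2),
      "%, sensitivity ", round(x$metrics$sensitivity, 2),
      "%, specificity ", round(x$metrics$specificity, 2), "%\n",
      "  test Dice: disc ", round(x$seg_dice[["disc"]], 3),
      ", cup ", round(x$seg_dice[["cup"]], 3), "\n", sep = "")
  invisible(x)
}

#' Per-image screening results
#'
#' @param x A `screening_result`.
#' @param ... Unused.
#' @return Tibble with one row per image: split, true/predicted labels,
#'   class probabilities, and true/estimated CDR.
#' @export
tidy.screening_result <- function(x, ...) x$per_image

#' One-row summary of a screening run
#'
#' @param x A `screening_result`.
#' @param ... Unused.
#' @export
glance.screening_result <- function(x, ...) {
  dplyr::bind_cols(x$metrics,
                   tibble::tibble(dice_disc = x$seg_dice[["disc"]],
                                  dice_cup = x$seg_dice[["cup"]],
                                  n_test = sum(x$per_image$split == "test")))
}

#' Classification-probability plot for a screening run
#'
#' @param object A `screening_result`.
#' @param ... Unused.
#' @export
autoplot.screening_result <- function(object, ...) {
  df <- dplyr::filter(object$per_image, .data$split == "test")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$p_glaucoma,
                                   colour = .data$predicted_label)) +
    ggplot2::geom_jitter(width = 0.15, height = 0) +
    ggplot2::labs(x = "true label", y = "p(glaucoma)",
                  title = "Test-set class-capsule norms")
}
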