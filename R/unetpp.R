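#' Configure the UNet++ segmenter
#'
#' The segmenter is an encoder--decoder with the UNet++ nested dense skip
#' pattern: every decoder node `X(i, j)` receives all earlier nodes of its
#' level `X(i, 0..j-1)` plus an upsampled `X(i+1, j-1)`, which re-exposes
#' high-resolution texture to the decoder at every depth. The model maps an
#' `H x W x in_channels` image to per-pixel disc and cup probabilities.
#'
#' @param depth Number of encoder levels below the top (input side must be
#'   divisible by `2^depth`).
#' @param base_filters Channel count of the first level; level `i` uses
#'   `base_filters * 2^i`.
#' @param dropout_rate Dropout probability applied after each conv block
#'   during training, in `[0, 1)`.
#' @param learning_rate Adam learning rate.
#' @param binarize_threshold Probability threshold used by [segment()].
#' @param deep_supervision If `TRUE`, every top-level decoder node gets its
#'   own head and their logits are averaged.
#' @return An object of class `seg_config`.
#' @export
seg_config <- function(depth = 4, base_filters = 16, dropout_rate = 0,
                       learning_rate = 1e-4, binarize_threshold = 0.5,
                       deep_supervision = FALSE) {
  stopifnot(depth >= 1, base_filters >= 1,
            dropout_rate >= 0, dropout_rate < 1,
            learning_rate > 0,
            binarize_threshold > 0, binarize_threshold < 1)
  structure(list(depth = as.integer(depth),
                 base_filters = as.integer(round(base_filters)),
                 dropout_rate = dropout_rate,
                 learning_rate = learning_rate,
                 binarize_threshold = binarize_threshold,
                 deep_supervision = isTRUE(deep_supervision)),
            class = "seg_config")
}

#' Build a UNet++ segmentation model
#'
#' Instantiates all conv-block parameters (two 3x3 same-padded convolutions
#' per node, He-initialized from `seed`) for the nested-skip topology. The
#' parameter count is a deterministic function of `(depth, base_filters)`.
#'
#' @param config A [seg_config()].
#' @param in_channels Input image channels (3 for RGB fundus images).
#' @param out_channels Output mask channels (2: optic disc, optic cup).
#' @param seed Integer seed for weight initialization.
#' @return An object of class `unetpp_model`.
#' @export
build_segmenter <- function(config, in_channels = 3, out_channels = 2,
                            seed = 1L) {
  stopifnot(inherits(config, "seg_config"))
  d <- config$depth
  ch <- config$base_filters * 2^(0:d)
  params <- withr::with_seed(seed, {
    p <- list()
    blk <- function(name, cin, cout) {
      p[[paste0(name, "a.W")]] <<- he_conv(3, cin, cout)
      p[[paste0(name, "a.b")]] <<- numeric(cout)
      p[[paste0(name, "b.W")]] <<- he_conv(3, cout, cout)
      p[[paste0(name, "b.b")]] <<- numeric(cout)
    }
    for (i in 0:d)
      blk(sprintf("x%d_0", i), if (i == 0) in_channels else ch[i], ch[i + 1])
    for (j in 1:d)
      for (i in 0:(d - j))
        blk(sprintf("x%d_%d", i, j), j * ch[i + 1] + ch[i + 2], ch[i + 1])
    heads <- if (config$deep_supervision) 1:d else d
    for (j in heads) {
      p[[sprintf("head%d.W", j)]] <- he_conv(1, ch[1], out_channels)
      p[[sprintf("head%d.b", j)]] <- numeric(out_channels)
    }
    p
  })
  structure(list(params = params, config = config,
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 adam = NULL),
            class = "unetpp_model")
}

#' @export
print.unetpp_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, 0L))
  cat("<unetpp_model> depth ", x$config$depth, ", base filters ",
      x$config$base_filters, ", ", np, " parameters\n", sep = "")
  invisible(x)
}

seg_check_input <- function(model, x) {
  d <- model$config$depth
  if (dim(x)[1] %% 2^d != 0 || dim(x)[2] %% 2^d != 0)
    stop("input side ", dim(x)[1], "x", dim(x)[2],
         " not divisible by 2^depth = ", 2^d)
  if (dim(x)[3] != model$in_channels)
    stop("expected ", model$in_channels, " input channels")
}

# Forward pass on the tape; returns prob array + tape/node ids for backprop.
seg_forward <- function(model, x, train = FALSE) {
  seg_check_input(model, x)
  cfg <- model$config
  d <- cfg$depth
  tp <- tape_new(model$params, train = train)
  xin <- t_input(tp, x)
  node <- matrix(NA_integer_, d + 1, d + 1)   # [i+1, j+1]
  blk <- function(id, name) {
    id <- t_relu(tp, t_conv(tp, id, paste0(name, "a"), pad = 1L))
    id <- t_relu(tp, t_conv(tp, id, paste0(name, "b"), pad = 1L))
    t_dropout(tp, id, cfg$dropout_rate)
  }
  for (i in 0:d) {
    inp <- if (i == 0) xin else t_pool(tp, node[i, 1])
    node[i + 1, 1] <- blk(inp, sprintf("x%d_0", i))
  }
  for (j in 1:d)
    for (i in 0:(d - j)) {
      inp <- t_concat(tp, c(node[i + 1, 1:j],
                            t_up(tp, node[i + 2, j])))
      node[i + 1, j + 1] <- blk(inp, sprintf("x%d_%d", i, j))
    }
  heads <- if (cfg$deep_supervision) 1:d else d
  logit_ids <- vapply(heads, function(j)
    t_conv(tp, node[1, j + 1], sprintf("head%d", j)), 0L)
  if (length(logit_ids) > 1) {
    acc <- tp$vals[[logit_ids[1]]]
    for (k in 2:length(logit_ids)) acc <- acc + tp$vals[[logit_ids[k]]]
    # average of logits via a concat-free trick: record as pseudo step
    mean_id <- t_put(tp, acc / length(logit_ids),
                     list(op = "mean_heads", inputs = logit_ids,
                          cache = list(k = length(logit_ids))))
  } else {
    mean_id <- logit_ids[1]
  }
  out_id <- t_sigmoid(tp, mean_id)
  list(prob = tp$vals[[out_id]], tp = tp, out_id = out_id)
}

#' Segment an image into optic-disc and optic-cup masks
#'
#' Thresholds the model's per-pixel probabilities and constrains the cup
#' mask to lie inside the disc mask (their intersection), reflecting the
#' anatomy of the optic nerve head.
#'
#' @param model A trained (or untrained) [build_segmenter()] model.
#' @param image `H x W x in_channels` array with sides divisible by
#'   `2^depth`.
#' @param binarize_threshold Optional override of the configured threshold;
#'   a pixel is in the mask when its probability is strictly above it.
#' @return A list with logical matrices `disc` and `cup`
#'   (`cup` always a subset of `disc`) and the probability array `prob`.
#' @export
segment <- function(model, image, binarize_threshold = NULL) {
  stopifnot(inherits(model, "unetpp_model"))
  thr <- binarize_threshold %||% model$config$binarize_threshold
  prob <- seg_forward(model, image, train = FALSE)$prob
  disc <- prob[, , 1] > thr
  cup <- (prob[, , 2] > thr) & disc
  list(disc = disc, cup = cup, prob = prob)
}

seg_sample_loss_grad <- function(prob, mask, eps = 1) {
  C <- dim(prob)[3]
  npx <- prod(dim(prob)[1:2])
  loss <- 0
  dprob <- array(0, dim = dim(prob))
  for (c in seq_len(C)) {
    p <- pmin(pmax(prob[, , c], 1e-7), 1 - 1e-7)
    y <- mask[, , c]
    bce <- -mean(y * log(p) + (1 - y) * log(1 - p))
    I <- sum(p * y); S <- sum(p) + sum(y)
    dce <- (2 * I + eps) / (S + eps)
    loss <- loss + bce + (1 - dce)
    dbce <- (p - y) / (p * (1 - p)) / npx
    ddice <- (2 * y * (S + eps) - (2 * I + eps)) / (S + eps)^2
    dprob[, , c] <- (dbce - ddice) / C
  }
  list(loss = loss / C, dprob = dprob)
}

as_sample_list <- function(x) {
  if (is.list(x)) return(x)
  if (is.array(x) && length(dim(x)) == 4)
    return(lapply(seq_len(dim(x)[4]), function(i) x[, , , i]))
  stop("expected a list of arrays or a 4-D array")
}

#' Train the UNet++ segmenter
#'
#' Minimizes binary cross-entropy plus soft-Dice loss (smoothing eps = 1),
#' averaged over the disc and cup channels, with Adam at the configured
#' learning rate. A fraction of the samples is held out for validation and
#' early stopping (patience epochs without a validation-loss improvement);
#' the best-validation parameters are restored at the end.
#'
#' @param model A [build_segmenter()] model.
#' @param images List of `H x W x C` arrays (or a 4-D array).
#' @param masks List of `H x W x 2` arrays (disc, cup), aligned with
#'   `images`.
#' @param epochs Maximum number of epochs.
#' @param seed Seed controlling the holdout split, shuffling and dropout.
#' @param patience Early-stopping patience in epochs (`Inf` disables).
#' @param val_fraction Fraction of samples held out (at least 1 sample).
#' @return An object of class `seg_fit`: the trained `model`, a `trace`
#'   tibble (`epoch`, `train_loss`, `val_loss`, `val_dice_disc`,
#'   `val_dice_cup`) and `best_epoch`.
#' @export
train_segmenter <- function(model, images, masks, epochs = 30, seed = 1L,
                            patience = 10, val_fraction = 0.2) {
  stopifnot(inherits(model, "unetpp_model"))
  images <- as_sample_list(images)
  masks <- as_sample_list(masks)
  n <- length(images)
  if (n < 2)
    stop("need at least 2 samples for a validation holdout")
  if (all(vapply(masks, function(m) sum(m) == 0, TRUE)))
    warning("all-background masks in training set")
  res <- withr::with_seed(seed, {
    n_val <- max(1L, round(val_fraction * n))
    val_idx <- sample(n, n_val)
    tr_idx <- setdiff(seq_len(n), val_idx)
    params <- model$params
    adam <- adam_new(params)
    best <- list(loss = Inf, params = params, epoch = 0L)
    wait <- 0L
    rows <- vector("list", epochs)
    mdl <- model
    for (ep in seq_len(epochs)) {
      tr_loss <- 0
      for (i in sample(tr_idx)) {
        mdl$params <- params
        fw <- seg_forward(mdl, images[[i]], train = TRUE)
        lg <- seg_sample_loss_grad(fw$prob, masks[[i]])
        tr_loss <- tr_loss + lg$loss
        grads <- tape_backward(fw$tp, fw$out_id, lg$dprob)
        st <- adam_step(params, grads, adam, model$config$learning_rate)
        params <- st$params; adam <- st$state
      }
      tr_loss <- tr_loss / length(tr_idx)
      mdl$params <- params
      val_loss <- 0; vd_disc <- 0; vd_cup <- 0
      for (i in val_idx) {
        fw <- seg_forward(mdl, images[[i]], train = FALSE)
        val_loss <- val_loss + seg_sample_loss_grad(fw$prob, masks[[i]])$loss
        sg <- segment(mdl, images[[i]])
        vd_disc <- vd_disc + dice(sg$disc, masks[[i]][, , 1] > 0.5)
        vd_cup <- vd_cup + dice(sg$cup, masks[[i]][, , 2] > 0.5)
      }
      val_loss <- val_loss / n_val
      rows[[ep]] <- tibble::tibble(
        epoch = ep, train_loss = tr_loss, val_loss = val_loss,
        val_dice_disc = vd_disc / n_val, val_dice_cup = vd_cup / n_val)
      if (val_loss < best$loss) {
        best <- list(loss = val_loss, params = params, epoch = ep)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    }
    list(params = best$params, trace = dplyr::bind_rows(rows),
         best_epoch = best$epoch)
  })
  model$params <- res$params
  structure(list(model = model, trace = res$trace,
                 best_epoch = res$best_epoch),
            class = "seg_fit")
}

#' @export
print.seg_fit <- function(x, ...) {
  last <- x$trace[nrow(x$trace), ]
  cat("<seg_fit> ", nrow(x$trace), " epochs (best at ", x$best_epoch,
      "), val Dice disc ", round(last$val_dice_disc, 3),
      ", cup ", round(last$val_dice_cup, 3), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.seg_fit <- function(x, ...) x$trace

#' @export
glance.seg_fit <- function(x, ...) {
  best <- x$trace[x$trace$epoch == x$best_epoch, ]
  tibble::tibble(epochs = nrow(x$trace), best_epoch = x$best_epoch,
                 val_loss = best$val_loss,
                 val_dice_disc = best$val_dice_disc,
                 val_dice_cup = best$val_dice_cup)
}

#' Training-curve plot for a segmenter fit
#'
#' @param object A `seg_fit`.
#' @param ... Unused.
#' @export
autoplot.seg_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$trace, -"epoch",
                            names_to = "series", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = NULL, title = "UNet++ training")
}

#' Dice coefficient of two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`, with the empty-vs-empty pair defined
#' as 1 (perfect agreement on absence).
#'
#' @param mask_a,mask_b Logical/0-1 matrices of equal shape.
#' @return A number in `[0, 1]`.
#' @export
dice <- function(mask_a, mask_b) {
  stopifnot(all(dim(mask_a) == dim(mask_b)))
  a <- mask_a > 0; b <- mask_b > 0
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  2 * sum(a & b) / s
}

#' Intersection-over-union of two binary masks
#'
#' `|A intersect B| / |A union B|`, with empty-vs-empty defined as 1.
#'
#' @inheritParams dice
#' @return A number in `[0, 1]`.
#' @export
iou <- function(mask_a, mask_b) {
  stopifnot(all(dim(mask_a) == dim(mask_b)))
  a <- mask_a > 0; b <- mask_b > 0
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

#' The 4-D hyperparameter box that GWO searches over
#'
#' Maps the GWO search vector onto the segmenter's hyperparameters:
#' `log10(learning_rate)` in `[-5, -2]`, `dropout_rate` in `[0, 0.5]`,
#' `base_filters` in `[8, 32]` (rounded on decoding), `binarize_threshold`
#' in `[0.2, 0.8]`.
#'
#' @return An object of class `seg_search_space` (a tibble with `param`,
#'   `lower`, `upper`).
#' @export
seg_search_space <- function() {
  structure(
    tibble::tibble(
      param = c("log10_lr", "dropout_rate", "base_filters",
                "binarize_threshold"),
      lower = c(-5, 0, 8, 0.2),
      upper = c(-2, 0.5, 32, 0.8)),
    class = c("seg_search_space", "tbl_df", "tbl", "data.frame"))
}

#' Decode a GWO search vector into a segmenter configuration
#'
#' @param vec Numeric vector of length `nrow(space)` inside the box.
#' @param space A [seg_search_space()].
#' @param depth Encoder depth of the decoded configuration.
#' @return A [seg_config()].
#' @export
decode_seg_config <- function(vec, space = seg_search_space(), depth = 2) {
  stopifnot(length(vec) == nrow(space))
  v <- stats::setNames(as.numeric(vec), space$param)
  seg_config(depth = depth,
             base_filters = round(unname(v["base_filters"])),
             dropout_rate = unname(v["dropout_rate"]),
             learning_rate = unname(10^v["log10_lr"]),
             binarize_threshold = unname(v["binarize_threshold"]))
}

#' Tune the segmenter's hyperparameters with Grey Wolf Optimization
#'
#' Runs [gwo_optimize()] over the hyperparameter box. Each wolf position is
#' decoded into a [seg_config()]; a fresh model is short-trained for
#' `budget_epochs` on a fixed internal train/validation split, and the
#' fitness handed to the optimizer is `1 - mean validation Dice` (disc and
#' cup averaged). Diverging evaluations surface as `+Inf` fitness and the
#' search continues.
#'
#' @param images,masks Sample lists as in [train_segmenter()].
#' @param space A [seg_search_space()].
#' @param gwo_config A [gwo_config()] whose `dim` equals `nrow(space)` and
#'   whose bounds are taken from the space (they are overridden if they
#'   disagree).
#' @param budget_epochs Short-training epochs per evaluation.
#' @param depth Encoder depth used for every candidate.
#' @param eval_seed Seed reused for every candidate evaluation so fitness
#'   differences reflect hyperparameters, not initialization noise.
#' @return An object of class `seg_tuning`: `best_config`, `result`
#'   (the `gwo_result`), `space`.
#' @export
gwo_tune_segmenter <- function(images, masks, space = seg_search_space(),
                               gwo_config, budget_epochs = 5, depth = 2,
                               eval_seed = 99L) {
  stopifnot(inherits(gwo_config, "gwo_config"),
            gwo_config$dim == nrow(space))
  gwo_config$lower_bounds <- space$lower
  gwo_config$upper_bounds <- space$upper
  images <- as_sample_list(images)
  masks <- as_sample_list(masks)
  objective <- function(vec) {
    cfg <- decode_seg_config(vec, space, depth)
    mdl <- build_segmenter(cfg, in_channels = dim(images[[1]])[3],
                           seed = eval_seed)
    fit <- tryCatch(
      train_segmenter(mdl, images, masks, epochs = budget_epochs,
                      seed = eval_seed, patience = Inf),
      error = function(e) NULL)
    if (is.null(fit)) return(Inf)
    last <- fit$trace[nrow(fit$trace), ]
    1 - (last$val_dice_disc + last$val_dice_cup) / 2
  }
  res <- gwo_optimize(objective, gwo_config)
  structure(list(best_config = decode_seg_config(res$best_position, space,
                                                 depth),
                 result = res, space = space),
            class = "seg_tuning")
}

#' @export
print.seg_tuning <- function(x, ...) {
  cat("<seg_tuning> best fitness ", format(x$result$best_fitness),
      " (1 - mean val Dice)\n", sep = "")
  utils::str(unclass(x$best_config))
  invisible(x)
}

#' @export
tidy.seg_tuning <- function(x, ...) x$result$trace

#' @export
glance.seg_tuning <- function(x, ...) glance(x$result)

`%||%` <- function(a, b) if (is.null(a)) b else a
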