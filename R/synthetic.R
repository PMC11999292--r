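#' Parameters of the synthetic fundus generator
#'
#' The generator emulates the screening inputs the pipeline consumes:
#' fundus-like RGB rasters with a bright elliptical optic disc, a brighter
#' inner cup whose diameter ratio to the disc (CDR) defines the class,
#' dark vessel-like curves crossing the disc, and the aberrations typical
#' of fundus archives -- blur, brightness jitter and sensor noise. Class
#' separability is a guarantee by construction: the glaucoma CDR range lies
#' entirely above the normal range.
#'
#' @param image_side Raster side in pixels (128 for segmentation sets,
#'   64 for classification crops).
#' @param disc_radius_range Disc semi-major axis as a fraction of the side.
#' @param cdr_normal,cdr_glaucoma Cup-to-disc diameter-ratio ranges of the
#'   two classes; both inside `(0, 1)` and non-overlapping with
#'   `cdr_glaucoma` above.
#' @param vessel_count Integer range of vessel strokes per image.
#' @param noise_sigma Additive Gaussian noise s.d. (intensity units, images
#'   live in `[0, 1]`).
#' @param blur_sigma_range Per-image Gaussian blur s.d. range (pixels).
#' @param brightness_jitter Additive brightness offset range.
#' @param seed Integer seed; the full dataset is a pure function of
#'   `(params, seed)`.
#' @return An object of class `fundus_params`.
#' @export
fundus_params <- function(image_side = 128,
                          disc_radius_range = c(0.15, 0.25),
                          cdr_normal = c(0.2, 0.4),
                          cdr_glaucoma = c(0.6, 0.85),
                          vessel_count = c(3, 6),
                          noise_sigma = 0.02,
                          blur_sigma_range = c(0, 1.2),
                          brightness_jitter = c(-0.08, 0.08),
                          seed = 1L) {
  stopifnot(image_side >= 32,
            all(cdr_normal > 0), all(cdr_normal < 1),
            all(cdr_glaucoma > 0), all(cdr_glaucoma < 1),
            max(cdr_normal) < min(cdr_glaucoma))
  structure(list(image_side = as.integer(image_side),
                 disc_radius_range = disc_radius_range,
                 cdr_normal = cdr_normal, cdr_glaucoma = cdr_glaucoma,
                 vessel_count = as.integer(vessel_count),
                 noise_sigma = noise_sigma,
                 blur_sigma_range = blur_sigma_range,
                 brightness_jitter = brightness_jitter,
                 seed = as.integer(seed)),
            class = "fundus_params")
}

# Range draw that consumes exactly one variate even when lo == hi, so
# degenerate parameter ranges never shift the RNG stream.
runif_range <- function(lo, hi) lo + (hi - lo) * stats::runif(1)

ellipse_mask <- function(side, cx, cy, a, b) {
  X <- matrix(seq_len(side), side, side)
  Y <- matrix(seq_len(side), side, side, byrow = TRUE)
  ((X - cx) / a)^2 + ((Y - cy) / b)^2 <= 1
}

smooth_field <- function(side, sigma, amplitude) {
  f <- matrix(stats::runif(side * side, -1, 1), side, side)
  f <- as.matrix(EBImage::gblur(f, sigma = sigma))
  amplitude * f / max(abs(f) + 1e-12)
}

draw_vessel <- function(canvas_dim, cx, cy, width = 1.5) {
  side <- canvas_dim
  edges <- list(c(1, stats::runif(1, 1, side)),
                c(side, stats::runif(1, 1, side)),
                c(stats::runif(1, 1, side), 1),
                c(stats::runif(1, 1, side), side))
  ends <- sample(4, 2)
  p0 <- edges[[ends[1]]]; p2 <- edges[[ends[2]]]
  p1 <- c(cx, cy) + stats::rnorm(2, sd = side / 10)
  tt <- seq(0, 1, length.out = 4 * side)
  px <- (1 - tt)^2 * p0[1] + 2 * tt * (1 - tt) * p1[1] + tt^2 * p2[1]
  py <- (1 - tt)^2 * p0[2] + 2 * tt * (1 - tt) * p1[2] + tt^2 * p2[2]
  mask <- matrix(FALSE, side, side)
  w <- ceiling(width)
  for (k in seq_along(tt)) {
    r0 <- max(1, round(px[k]) - w); r1 <- min(side, round(px[k]) + w)
    c0 <- max(1, round(py[k]) - w); c1 <- min(side, round(py[k]) + w)
    for (r in r0:r1)
      for (cc in c0:c1)
        if ((r - px[k])^2 + (cc - py[k])^2 <= width^2)
          mask[r, cc] <- TRUE
  }
  mask
}

gen_one_sample <- function(params, label) {
  side <- params$image_side
  r_frac <- stats::runif(1, params$disc_radius_range[1],
                         params$disc_radius_range[2])
  a <- r_frac * side
  b <- a * stats::runif(1, 0.85, 1)
  cdr_range <- if (label == "glaucoma") params$cdr_glaucoma else
    params$cdr_normal
  cdr <- stats::runif(1, cdr_range[1], cdr_range[2])
  margin <- 1.1 * a
  ok <- FALSE
  for (try in 1:20) {
    cx <- stats::runif(1, margin, side - margin)
    cy <- stats::runif(1, margin, side - margin)
    if (cx - a >= 1 && cx + a <= side && cy - b >= 1 && cy + b <= side) {
      ok <- TRUE; break
    }
  }
  if (!ok) stop("could not place the disc inside the image bounds")
  off_lim <- 0.4 * (1 - cdr) * min(a, b)
  ocx <- cx + stats::runif(1, -off_lim, off_lim)
  ocy <- cy + stats::runif(1, -off_lim, off_lim)
  disc <- ellipse_mask(side, cx, cy, a, b)
  cup <- ellipse_mask(side, ocx, ocy, cdr * a, cdr * b)
  cup <- cup & disc

  base <- c(0.55, 0.28, 0.16)
  disc_col <- c(0.95, 0.82, 0.55)
  cup_col <- c(1.00, 0.93, 0.70)
  tex <- smooth_field(side, side / 16, 0.05)
  img <- array(0, dim = c(side, side, 3))
  for (ch in 1:3) {
    plane <- base[ch] + tex
    plane[disc] <- disc_col[ch]
    plane[cup] <- cup_col[ch]
    img[, , ch] <- plane
  }
  nves <- sample(params$vessel_count[1]:params$vessel_count[2], 1)
  for (v in seq_len(nves)) {
    vm <- draw_vessel(side, cx, cy, width = stats::runif(1, 1, 2))
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[vm] <- plane[vm] * 0.45
      img[, , ch] <- plane
    }
  }
  blur <- runif_range(params$blur_sigma_range[1],
                      params$blur_sigma_range[2])
  if (blur > 0.05)
    for (ch in 1:3)
      img[, , ch] <- as.matrix(EBImage::gblur(img[, , ch], sigma = blur))
  img <- img + runif_range(params$brightness_jitter[1],
                           params$brightness_jitter[2])
  img <- img + array(stats::rnorm(length(img), sd = params$noise_sigma),
                     dim = dim(img))
  img <- pmin(pmax(img, 0), 1)
  list(image = img, disc_mask = disc, cup_mask = cup,
       label = label, cdr = cdr,
       provenance = list(cx = cx, cy = cy, a = a, b = b, cdr = cdr,
                         blur_sigma = blur, n_vessels = nves))
}

#' Generate a labelled synthetic fundus dataset
#'
#' Draws `n_per_class` glaucomatous and normal samples from the seeded
#' generator. Masks are rendered from the exact disc/cup geometry before any
#' degradation, so blur, jitter and noise never alter the ground truth; the
#' cup mask is always contained in the disc mask, and the measured
#' (rasterized) CDR stays within 2% of the drawn target.
#'
#' @param params A [fundus_params()].
#' @param n_per_class Samples per class (>= 1).
#' @return An object of class `fundus_dataset`: `samples` (list with
#'   `image`, `disc_mask`, `cup_mask`, `label`, `cdr`, `provenance`) and
#'   `manifest` (tibble: `id`, `label`, `cdr`).
#' @export
#' @examples
#' ds <- generate_fundus_dataset(fundus_params(image_side = 64, seed = 3), 2)
#' ds$manifest
generate_fundus_dataset <- function(params, n_per_class) {
  stopifnot(inherits(params, "fundus_params"), n_per_class >= 1)
  samples <- withr::with_seed(params$seed, {
    labs <- rep(c("normal", "glaucoma"), each = n_per_class)
    lapply(labs, function(lb) gen_one_sample(params, lb))
  })
  manifest <- tibble::tibble(
    id = sprintf("s%03d", seq_along(samples)),
    label = vapply(samples, `[[`, "", "label"),
    cdr = vapply(samples, `[[`, 0.0, "cdr"))
  structure(list(samples = samples, manifest = manifest, params = params),
            class = "fundus_dataset")
}

#' @export
print.fundus_dataset <- function(x, ...) {
  cat("<fundus_dataset> ", length(x$samples), " samples (",
      sum(x$manifest$label == "glaucoma"), " glaucoma / ",
      sum(x$manifest$label == "normal"), " normal), side ",
      x$params$image_side, " px\n", sep = "")
  invisible(x)
}

#' Measured cup-to-disc ratio of a rasterized mask pair
#'
#' Diameters are estimated from the second moments of the mask pixels: for
#' a filled ellipse the projection variance is proportional to the squared
#' axis, so the ratio of root summed variances (with the 1/12
#' pixel-quantization variance removed) recovers the diameter ratio. This
#' is robust to the one-pixel rasterization jitter that plagues
#' bounding-box extents on small cups.
#'
#' @param disc_mask,cup_mask Logical matrices.
#' @return A number (`NA` if either mask is empty).
#' @export
mask_cdr <- function(disc_mask, cup_mask) {
  v2 <- function(m) {
    w <- which(m, arr.ind = TRUE)
    if (nrow(w) < 2) return(NA_real_)
    max(stats::var(w[, 1]) + stats::var(w[, 2]) - 1 / 6, 0)
  }
  sqrt(v2(cup_mask) / v2(disc_mask))
}

#' Stratified train/test split of a manifest
#'
#' Splits per class so that `round(n * train_fraction)` of each class lands
#' in the training set; the two parts are disjoint and exhaustive.
#'
#' @param manifest A tibble with at least `id` and `label` columns.
#' @param train_fraction In `(0, 1)`.
#' @param stratify Split within each label (default) or overall.
#' @param seed Integer seed.
#' @return A list of tibbles `train` and `test`.
#' @export
split_dataset <- function(manifest, train_fraction = 0.8, stratify = TRUE,
                          seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1,
            all(c("id", "label") %in% names(manifest)))
  withr::with_seed(seed, {
    take <- function(df) {
      n_tr <- round(nrow(df) * train_fraction)
      idx <- sample(nrow(df), n_tr)
      list(train = df[idx, ], test = df[-idx, ])
    }
    if (stratify) {
      groups <- split(manifest, manifest$label)
      if (any(vapply(groups, nrow, 0L) < 2))
        stop("stratified split needs at least 2 members per class")
      parts <- lapply(groups, take)
      list(train = dplyr::bind_rows(lapply(parts, `[[`, "train")),
           test = dplyr::bind_rows(lapply(parts, `[[`, "test")))
    } else {
      take(manifest)
    }
  })
}

#' Write a synthetic dataset to disk
#'
#' Images as RGB PNG, masks as single-channel PNG with values {0, 255},
#' plus a `manifest.csv` with columns `id`, `image_path`, `disc_mask_path`,
#' `cup_mask_path`, `label`, `cdr` -- the schema the segmentation and
#' classification stages consume.
#'
#' @param dataset A [generate_fundus_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return The manifest tibble (with paths), invisibly.
#' @export
write_fundus_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "fundus_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- dataset$manifest
  paths <- purrr::map2_dfr(dataset$samples, man$id, function(s, id) {
    ip <- file.path(dir, paste0(id, ".png"))
    dp <- file.path(dir, paste0(id, "_disc.png"))
    cp <- file.path(dir, paste0(id, "_cup.png"))
    png::writePNG(aperm(s$image, c(1, 2, 3)), ip)
    png::writePNG(s$disc_mask * 1.0, dp)
    png::writePNG(s$cup_mask * 1.0, cp)
    tibble::tibble(image_path = ip, disc_mask_path = dp, cup_mask_path = cp)
  })
  man <- dplyr::bind_cols(man[, "id"], paths, man[, c("label", "cdr")])
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}

#' Read a dataset written by [write_fundus_dataset()]
#'
#' @param manifest_path Path to `manifest.csv`.
#' @return A `fundus_dataset`-shaped list (`samples`, `manifest`).
#' @export
read_fundus_dataset <- function(manifest_path) {
  man <- tibble::as_tibble(utils::read.csv(manifest_path,
                                           stringsAsFactors = FALSE))
  base <- dirname(manifest_path)
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, basename(p)))
  samples <- lapply(seq_len(nrow(man)), function(i) {
    img <- png::readPNG(resolve(man$image_path[i]))
    list(image = img,
         disc_mask = png::readPNG(resolve(man$disc_mask_path[i])) > 0.5,
         cup_mask = png::readPNG(resolve(man$cup_mask_path[i])) > 0.5,
         label = man$label[i], cdr = man$cdr[i])
  })
  structure(list(samples = samples, manifest = man), class = "fundus_dataset")
}
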