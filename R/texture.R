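#' Patch-level texture descriptors and resolution-band energies
#'
#' Computes the textural quantities that drive the pack-allocation fitness:
#' per-patch local variance, local entropy (8-bin) and mean gradient
#' magnitude on non-overlapping patches, plus the fine/coarse
#' resolution-band energies of a 3-level Gaussian pyramid, a deterministic
#' 2-means classification misfit of the descriptors, and the descriptor
#' discrepancy between the image and a Gaussian pre-processed (sigma = 1)
#' version of it.
#'
#' The image is z-scored on entry, so every downstream quantity -- and hence
#' the pack-allocation score built from it -- is invariant to affine
#' rescaling of the raw intensities. A patch is flagged as variation-causing
#' (`omega = 1`) when any of its descriptors lies more than `tau` robust
#' standard deviations (median absolute deviation scale) from the patch
#' population median.
#'
#' @param image 2-D numeric matrix (grayscale), finite-valued.
#' @param patch_size Side of the square non-overlapping patches; the grid
#'   must contain at least 4 patches.
#' @param tau Variation-flag threshold in robust standard deviations.
#' @return An object of class `texture_features`: `patches` (a tibble with
#'   `row`, `col`, `variance`, `entropy`, `grad_mean`, `mean_int`, `omega`),
#'   `extf` (the stacked descriptor vector), `rho_high`, `rho_low`, `fc`,
#'   `fct`, `diff_org_ppc`, `patch_size`, `tau`.
#' @export
#' @examples
#' img <- matrix(rnorm(64 * 64), 64, 64)
#' tf <- extract_texture_features(img, patch_size = 8)
#' tf$rho_high > 0
extract_texture_features <- function(image, patch_size = 8, tau = 2) {
  stopifnot(is.matrix(image), all(is.finite(image)), patch_size >= 2)
  nr <- nrow(image) %/% patch_size
  nc <- ncol(image) %/% patch_size
  if (nr * nc < 4)
    stop("`patch_size` must yield at least 4 patches on this image")
  s <- stats::sd(image)
  degenerate <- !is.finite(s) || s == 0
  z <- if (degenerate) {
    warning("constant image: degenerate texture, all descriptors zero")
    image * 0
  } else {
    (image - mean(image)) / s
  }

  desc <- patch_descriptors(z, patch_size, nr, nc)
  omega <- variation_flags(as.matrix(desc[, c("variance", "entropy",
                                              "grad_mean")]), tau)
  desc$omega <- omega

  if (degenerate) {
    rho_high <- rho_low <- 0
    fc <- 0
    diff_ppc <- 0
  } else {
    bands <- pyramid_band_energies(z)
    rho_high <- bands$high
    rho_low <- bands$low
    fc <- kmeans2_misfit(as.matrix(desc[, c("variance", "entropy",
                                            "grad_mean")]))
    ppc <- as.matrix(gaussian_blur(z, 1))
    desc_ppc <- patch_descriptors(ppc, patch_size, nr, nc)
    d0 <- as.matrix(desc[, c("variance", "entropy", "grad_mean")])
    d1 <- as.matrix(desc_ppc[, c("variance", "entropy", "grad_mean")])
    diff_ppc <- mean(abs(d0 - d1))
  }

  structure(
    list(patches = desc,
         extf = as.numeric(as.matrix(desc[, c("variance", "entropy",
                                              "grad_mean")])),
         rho_high = rho_high, rho_low = rho_low,
         fc = fc, fct = nrow(desc) * 3L,
         diff_org_ppc = diff_ppc,
         patch_size = as.integer(patch_size), tau = tau),
    class = "texture_features")
}

# Per-patch descriptors on a (z-scored) grayscale matrix. Gradients are
# taken within each patch (replicated edge), so one noisy patch never
# bleeds into its neighbours' descriptors.
patch_descriptors <- function(z, patch_size, nr, nc) {
  rng <- range(z)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = 9)
  out <- vector("list", nr * nc)
  k <- 1L
  for (pc in seq_len(nc)) {
    for (pr in seq_len(nr)) {
      ri <- ((pr - 1) * patch_size + 1):(pr * patch_size)
      ci <- ((pc - 1) * patch_size + 1):(pc * patch_size)
      p <- z[ri, ci]
      cnt <- tabulate(findInterval(p, breaks, all.inside = TRUE), nbins = 8)
      pr_ <- cnt / sum(cnt)
      pr_ <- pr_[pr_ > 0]
      gx <- cbind(p[, -1, drop = FALSE], p[, ncol(p)]) - p
      gy <- rbind(p[-1, , drop = FALSE], p[nrow(p), ]) - p
      out[[k]] <- tibble::tibble(
        row = pr, col = pc,
        variance = stats::var(as.numeric(p)),
        entropy = -sum(pr_ * log2(pr_)),
        grad_mean = mean(sqrt(gx^2 + gy^2)),
        mean_int = mean(p))
      k <- k + 1L
    }
  }
  dplyr::bind_rows(out)
}

# omega = 1 iff any descriptor deviates from the patch-population median by
# more than tau robust SDs (MAD scale); exact at 0 when the column is flat.
variation_flags <- function(desc, tau) {
  score <- rep(0, nrow(desc))
  for (j in seq_len(ncol(desc))) {
    med <- stats::median(desc[, j])
    md <- stats::mad(desc[, j])
    dev <- abs(desc[, j] - med)
    sj <- if (md > 1e-12) dev / md else ifelse(dev > 1e-10, Inf, 0)
    score <- pmax(score, sj)
  }
  as.integer(score > tau)
}

# Fine band = image minus its sigma-1 blur; coarse band = twice blurred and
# twice decimated residual level. Energy = mean square.
pyramid_band_energies <- function(z) {
  g1 <- as.matrix(gaussian_blur(z, 1))
  fine <- z - g1
  d1 <- g1[seq(1, nrow(g1), by = 2), seq(1, ncol(g1), by = 2), drop = FALSE]
  g2 <- as.matrix(gaussian_blur(d1, 1))
  d2 <- g2[seq(1, nrow(g2), by = 2), seq(1, ncol(g2), by = 2), drop = FALSE]
  list(high = mean(fine^2), low = mean(d2^2))
}

gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  EBImage::gblur(x, sigma = sigma)
}

# Deterministic 2-means misfit: Lloyd iterations seeded at the two rows
# farthest apart, so no RNG is consumed.
kmeans2_misfit <- function(desc) {
  u <- unique(desc)
  if (nrow(u) < 2) return(0)
  d <- as.matrix(stats::dist(desc))
  far <- which(d == max(d), arr.ind = TRUE)[1, ]
  centers <- desc[c(far[1], far[2]), , drop = FALSE]
  km <- suppressWarnings(
    stats::kmeans(desc, centers = centers, iter.max = 50,
                  algorithm = "Lloyd"))
  km$tot.withinss
}

#' Pack-allocation score of a texture feature set
#'
#' The scalar score that pack allocation assigns to an image given a pack
#' count: the mean extracted descriptor, minus the classification-misfit
#' penalty `(fc / fct)` weighted by the inverse total resolution-band energy
#' `1 / (rho_high + rho_low)`, plus `pack_count - 1`. The sequential
#' differentiation term accumulates `pack_count - (rho_high + rho_low)` over
#' the patch index.
#'
#' @param features A [extract_texture_features()] result.
#' @param pack_count Positive integer number of allocated packs.
#' @return An object of class `allocation_score` with fields `F_dP`,
#'   `diff_time`, `seq_diff`, `pack_count`.
#' @export
pack_allocation_score <- function(features, pack_count = 1L) {
  stopifnot(inherits(features, "texture_features"),
            pack_count >= 1)
  if (features$fct <= 0) stop("`fct` must be positive")
  rho_sum <- features$rho_high + features$rho_low
  if (rho_sum <= 0)
    stop("zero total resolution-band energy (constant image?)")
  F_dP <- (mean(features$extf) - (features$fc / features$fct) / rho_sum) +
    pack_count - 1
  n_patch <- nrow(features$patches)
  structure(
    list(F_dP = F_dP,
         diff_time = features$diff_org_ppc,
         seq_diff = n_patch * (pack_count - rho_sum),
         pack_count = as.integer(pack_count)),
    class = "allocation_score")
}

#' @export
print.allocation_score <- function(x, ...) {
  cat("<allocation_score> F(d,P) = ", format(x$F_dP),
      ", packs = ", x$pack_count, "\n", sep = "")
  invisible(x)
}

#' Texture-differentiation fitness of a candidate segmentation
#'
#' With a reference mask, returns `1 - Dice(predicted, reference)` (0 is
#' perfect, 1 is disjoint) so the quantity can be minimized directly. Without
#' a reference, returns the negated texture contrast between the patches
#' inside and outside the predicted mask: patches are assigned by majority
#' mask coverage, the per-patch descriptors (variance, entropy, gradient
#' mean, mean intensity) are column-standardized, and the contrast is the
#' Euclidean distance between the inside and outside descriptor centroids.
#' Masks that separate distinct textures (for instance a bright smooth optic
#' disc from a noisy background) therefore score lower (better).
#'
#' @param image 2-D numeric matrix.
#' @param predicted_mask Logical/0-1 matrix, same shape as `image`.
#' @param reference_mask Optional logical/0-1 matrix for supervised fitness.
#' @param patch_size Patch side for the unsupervised contrast.
#' @return A single number; lower is better.
#' @export
segmentation_fitness <- function(image, predicted_mask,
                                 reference_mask = NULL, patch_size = 8) {
  stopifnot(is.matrix(image),
            all(dim(predicted_mask) == dim(image)))
  pred <- predicted_mask > 0
  if (!is.null(reference_mask)) {
    stopifnot(all(dim(reference_mask) == dim(image)))
    return(1 - dice(pred, reference_mask > 0))
  }
  s <- stats::sd(image)
  z <- if (s > 0) (image - mean(image)) / s else image * 0
  nr <- nrow(image) %/% patch_size
  nc <- ncol(image) %/% patch_size
  desc <- patch_descriptors(z, patch_size, nr, nc)
  cov <- numeric(nrow(desc))
  k <- 1L
  for (pc in seq_len(nc)) {
    for (pr in seq_len(nr)) {
      ri <- ((pr - 1) * patch_size + 1):(pr * patch_size)
      ci <- ((pc - 1) * patch_size + 1):(pc * patch_size)
      cov[k] <- mean(pred[ri, ci])
      k <- k + 1L
    }
  }
  inside <- cov > 0.5
  if (!any(inside) || all(inside)) return(0)
  m <- as.matrix(desc[, c("variance", "entropy", "grad_mean", "mean_int")])
  m <- scale(m)
  m[!is.finite(m)] <- 0
  contrast <- sqrt(sum((colMeans(m[inside, , drop = FALSE]) -
                          colMeans(m[!inside, , drop = FALSE]))^2))
  -contrast
}

#' Tidy per-patch texture descriptors
#'
#' @param x A `texture_features` object.
#' @param ... Unused.
#' @return The per-patch tibble (`row`, `col`, `variance`, `entropy`,
#'   `grad_mean`, `mean_int`, `omega`).
#' @export
tidy.texture_features <- function(x, ...) x$patches

#' Write per-patch texture descriptors to CSV
#'
#' One row per patch: `row`, `col`, `variance`, `entropy`, `grad_mean`,
#' `omega`.
#'
#' @param features A `texture_features` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_texture_csv <- function(features, path) {
  utils::write.csv(
    features$patches[, c("row", "col", "variance", "entropy", "grad_mean",
                         "omega")],
    path, row.names = FALSE)
  invisible(path)
}
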