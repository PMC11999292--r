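# Shared fixtures, generated once per test run and cached.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Small segmentation set: n per class at the given side.
seg_fixture <- function(side = 64, n_per_class = 5, seed = 101) {
  cached(sprintf("seg_%d_%d_%d", side, n_per_class, seed), {
    ds <- generate_fundus_dataset(fundus_params(image_side = side,
                                                seed = seed), n_per_class)
    list(dataset = ds,
         images = lapply(ds$samples, `[[`, "image"),
         masks = lapply(ds$samples, function(s)
           array(c(s$disc_mask, s$cup_mask), c(side, side, 2))),
         labels = ds$manifest$label)
  })
}

# A clean bright-disc grayscale image with its mask, for texture tests.
disc_image_fixture <- function(side = 64, radius = 12, seed = 7,
                               noise = 0.05) {
  cached(sprintf("disc_%d_%d_%d", side, radius, seed), {
    withr::with_seed(seed, {
      X <- matrix(seq_len(side), side, side)
      Y <- matrix(seq_len(side), side, side, byrow = TRUE)
      cx <- side / 2 + 6; cy <- side / 2 - 4
      mask <- (X - cx)^2 + (Y - cy)^2 <= radius^2
      img <- 0.3 + matrix(stats::rnorm(side^2, sd = noise), side, side)
      img[mask] <- 0.9
      list(image = img, mask = mask, cx = cx, cy = cy, radius = radius)
    })
  })
}

circle_mask <- function(side, cx, cy, radius) {
  X <- matrix(seq_len(side), side, side)
  Y <- matrix(seq_len(side), side, side, byrow = TRUE)
  (X - cx)^2 + (Y - cy)^2 <= radius^2
}
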