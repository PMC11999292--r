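test_that("constant images degrade gracefully and refuse a score", {
  img <- matrix(0.5, 32, 32)
  expect_warning(tf <- extract_texture_features(img), "constant")
  expect_true(all(tf$extf == 0))
  expect_true(all(tf$patches$omega == 0))
  expect_error(pack_allocation_score(tf), "energy")
})

test_that("a single high-variance patch is the only variation-flagged one", {
  set.seed(3)
  img <- matrix(0.4, 32, 32)
  rows <- 9:16; cols <- 17:24              # patch (row 2, col 3) at size 8
  img[rows, cols] <- img[rows, cols] + rnorm(64, sd = 0.3)
  tf <- extract_texture_features(img, patch_size = 8)
  flagged <- tf$patches[tf$patches$omega == 1, ]
  expect_equal(nrow(flagged), 1)
  expect_equal(c(flagged$row, flagged$col), c(2, 3))
  # brute-force oracle: the flagged patch is the variance outlier
  vars <- matrix(0, 4, 4)
  for (pr in 1:4) for (pc in 1:4)
    vars[pr, pc] <- var(as.numeric(
      img[((pr - 1) * 8 + 1):(pr * 8), ((pc - 1) * 8 + 1):(pc * 8)]))
  expect_equal(which(vars == max(vars), arr.ind = TRUE)[1, ],
               c(row = 2, col = 3))
})

test_that("pixel-scale checkerboards put their energy in the fine band", {
  img <- outer(1:64, 1:64, function(i, j) (i + j) %% 2)
  tf <- extract_texture_features(img, patch_size = 8)
  expect_gt(tf$rho_high, 10 * tf$rho_low)
})

test_that("the allocation score reproduces a hand-computed evaluation", {
  # a hand-built feature set: mean(extf) = 0.5, fc/fct = 6/12, rho sum = 2
  fake <- structure(
    list(extf = c(0.2, 0.4, 0.6, 0.8),
         rho_high = 1.5, rho_low = 0.5,
         fc = 6, fct = 12L, diff_org_ppc = 0.1,
         patches = tibble::tibble(row = 1:4, col = 1L, omega = 0L),
         patch_size = 8L, tau = 2),
    class = "texture_features")
  sc <- pack_allocation_score(fake, pack_count = 3)
  # [0.5 - (6/12) * (1/2)] + 3 - 1 = 2.25
  expect_equal(sc$F_dP, 2.25)
  expect_equal(sc$seq_diff, 4 * (3 - 2))
  expect_equal(sc$diff_time, 0.1)
  # fc = 0, pack = 1 collapses to mean(extf)
  fake$fc <- 0
  expect_equal(pack_allocation_score(fake, 1)$F_dP, 0.5)
})

test_that("the score is monotone: up in pack count, down in misfit", {
  set.seed(5)
  img <- matrix(runif(64 * 64), 64, 64)
  tf <- extract_texture_features(img)
  s1 <- pack_allocation_score(tf, 1)$F_dP
  s3 <- pack_allocation_score(tf, 3)$F_dP
  expect_gt(s3, s1)
  tf2 <- tf; tf2$fc <- tf$fc * 2
  expect_lt(pack_allocation_score(tf2, 1)$F_dP, s1)
})

test_that("the score is invariant to affine intensity rescaling", {
  set.seed(6)
  img <- matrix(runif(64 * 64), 64, 64)
  a <- pack_allocation_score(extract_texture_features(img), 2)
  b <- pack_allocation_score(extract_texture_features(3 + 5 * img), 2)
  expect_equal(a$F_dP, b$F_dP, tolerance = 1e-10)
  expect_equal(a$seq_diff, b$seq_diff, tolerance = 1e-10)
})

test_that("supervised fitness is 1 - Dice with its boundary cases", {
  fx <- disc_image_fixture()
  m <- fx$mask
  expect_equal(segmentation_fitness(fx$image, m, m), 0)
  expect_equal(segmentation_fitness(fx$image, !m, m), 1)
  empty <- matrix(FALSE, nrow(m), ncol(m))
  expect_equal(segmentation_fitness(fx$image, empty, m), 1)
  shifted <- circle_mask(64, fx$cx + 4, fx$cy, fx$radius)
  f <- segmentation_fitness(fx$image, shifted, m)
  expect_gt(f, 0); expect_lt(f, 1)
})

test_that("unsupervised fitness prefers the true disc over random masks", {
  fx <- disc_image_fixture()
  f_true <- segmentation_fitness(fx$image, fx$mask)
  set.seed(42)
  f_rand <- replicate(200, {
    cx <- runif(1, fx$radius + 1, 64 - fx$radius - 1)
    cy <- runif(1, fx$radius + 1, 64 - fx$radius - 1)
    segmentation_fitness(fx$image, circle_mask(64, cx, cy, fx$radius))
  })
  expect_gte(mean(f_true < f_rand), 0.95)
})

test_that("texture descriptors dump one CSV row per patch", {
  set.seed(8)
  tf <- extract_texture_features(matrix(runif(32 * 32), 32, 32))
  path <- withr::local_tempfile(fileext = ".csv")
  write_texture_csv(tf, path)
  got <- utils::read.csv(path)
  expect_equal(nrow(got), 16)
  expect_named(got, c("row", "col", "variance", "entropy", "grad_mean",
                      "omega"))
  expect_equal(nrow(tidy(tf)), 16)
})
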