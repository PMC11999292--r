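test_that("the built segmenter honours shape, range and seeding contracts", {
  cfg <- seg_config(depth = 2, base_filters = 8)
  m <- build_segmenter(cfg, in_channels = 3, out_channels = 2, seed = 5)
  x <- withr::with_seed(1, array(runif(64 * 64 * 3), c(64, 64, 3)))
  sg <- segment(m, x)
  expect_equal(dim(sg$prob), c(64, 64, 2))
  expect_true(all(sg$prob >= 0 & sg$prob <= 1))
  m2 <- build_segmenter(cfg, in_channels = 3, out_channels = 2, seed = 5)
  expect_identical(m$params, m2$params)
  m3 <- build_segmenter(cfg, in_channels = 3, out_channels = 2, seed = 6)
  expect_false(identical(m$params, m3$params))
  # indivisible spatial size fails before any training
  m4 <- build_segmenter(seg_config(depth = 4, base_filters = 8), seed = 1)
  x40 <- array(0, c(40, 40, 3))   # 40 is not divisible by 2^4
  expect_error(segment(m4, x40), "divisible")
})

test_that("thresholding boundaries and cup containment hold", {
  cfg <- seg_config(depth = 1, base_filters = 4)
  m <- build_segmenter(cfg, seed = 2)
  x <- withr::with_seed(2, array(runif(32 * 32 * 3), c(32, 32, 3)))
  sg0 <- segment(m, x, binarize_threshold = 1e-9)
  expect_true(all(sg0$disc))          # sigmoid output is strictly positive
  sg <- segment(m, x)
  expect_true(all(!sg$cup | sg$disc)) # cup subset of disc
})

test_that("dice and iou match hand counts and their inequalities", {
  A <- matrix(FALSE, 4, 4); A[2:3, 2:3] <- TRUE
  B <- matrix(FALSE, 4, 4); B[2:3, 3:4] <- TRUE   # overlap 2 of 4
  expect_equal(dice(A, B), 0.5)
  expect_equal(iou(A, B), 1 / 3)
  expect_equal(dice(A, A), 1)
  expect_equal(iou(A, A), 1)
  disj <- matrix(FALSE, 4, 4); disj[1, 1] <- TRUE
  expect_equal(dice(A, disj), 0)
  expect_equal(iou(A, disj), 0)
  empty <- matrix(FALSE, 4, 4)
  expect_equal(dice(empty, empty), 1)
  set.seed(3)
  for (k in 1:25) {
    a <- matrix(runif(64) > 0.5, 8, 8)
    b <- matrix(runif(64) > 0.5, 8, 8)
    expect_equal(dice(a, b), dice(b, a))
    expect_lte(iou(a, b), dice(a, b))
  }
})

test_that("training demands enough samples and warns on empty masks", {
  cfg <- seg_config(depth = 1, base_filters = 4)
  m <- build_segmenter(cfg, seed = 1)
  x <- list(array(runif(16 * 16 * 3), c(16, 16, 3)))
  y <- list(array(0, c(16, 16, 2)))
  expect_error(train_segmenter(m, x, y, epochs = 1), "at least 2")
  expect_warning(
    train_segmenter(m, c(x, x), c(y, y), epochs = 1, seed = 1),
    "all-background")
})

test_that("identical seeds give identical training traces", {
  fx <- seg_fixture(side = 32, n_per_class = 2, seed = 55)
  cfg <- seg_config(depth = 1, base_filters = 4, learning_rate = 1e-3,
                    dropout_rate = 0.2)
  m <- build_segmenter(cfg, seed = 3)
  f1 <- train_segmenter(m, fx$images, fx$masks, epochs = 2, seed = 8)
  f2 <- train_segmenter(m, fx$images, fx$masks, epochs = 2, seed = 8)
  expect_identical(f1$trace, f2$trace)
  f3 <- train_segmenter(m, fx$images, fx$masks, epochs = 2, seed = 9)
  expect_false(identical(f1$trace, f3$trace))
})

test_that("a short training run clearly beats the untrained model", {
  fx <- seg_fixture(side = 64, n_per_class = 4, seed = 13)
  cfg <- seg_config(depth = 2, base_filters = 8, learning_rate = 1e-3)
  m <- build_segmenter(cfg, seed = 7)
  untrained <- mean(vapply(seq_along(fx$images), function(i)
    dice(segment(m, fx$images[[i]])$disc, fx$masks[[i]][, , 1] > 0.5), 0.0))
  fit <- train_segmenter(m, fx$images, fx$masks, epochs = 10, seed = 7)
  best <- fit$trace$val_dice_disc[nrow(fit$trace)]
  expect_gte(best, untrained + 0.4)
  expect_gte(best, 0.7)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("the search-space decoding rounds and bounds as documented", {
  sp <- seg_search_space()
  expect_equal(nrow(sp), 4)
  cfg <- decode_seg_config(c(-3, 0.25, 15.6, 0.5), sp, depth = 2)
  expect_equal(cfg$learning_rate, 1e-3)
  expect_equal(cfg$base_filters, 16L)
  expect_equal(cfg$dropout_rate, 0.25)
  expect_equal(cfg$binarize_threshold, 0.5)
  expect_error(decode_seg_config(c(1, 2), sp), "length")
})

test_that("a collapsed search box returns that point with a flat trace", {
  fx <- seg_fixture(side = 32, n_per_class = 2, seed = 21)
  eps <- 1e-9
  sp <- seg_search_space()
  sp$upper <- sp$lower + eps
  gcfg <- gwo_config(3, 4, 2, sp$lower, sp$upper, seed = 1)
  tune <- gwo_tune_segmenter(fx$images, fx$masks, space = sp,
                             gwo_config = gcfg, budget_epochs = 1,
                             depth = 1, eval_seed = 3)
  expect_equal(tune$best_config$learning_rate, 10^sp$lower[1],
               tolerance = 1e-6)
  expect_equal(tune$best_config$base_filters, round(sp$lower[3]))
  h <- tune$result$history
  expect_true(all(abs(h - h[1]) < 1e-9))
  expect_true(all(diff(h) <= 0))
})
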