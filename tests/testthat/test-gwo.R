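sphere <- function(z) sum(z^2)

test_that("pack initialization respects bounds, ranks leaders, and is seeded", {
  cfg <- gwo_config(30, 2, 50, c(-3, 0), c(2, 5), seed = 4)
  pack <- initialize_pack(cfg, sphere)
  expect_true(all(sweep(pack$positions, 2, cfg$lower_bounds, `>=`)))
  expect_true(all(sweep(pack$positions, 2, cfg$upper_bounds, `<=`)))
  expect_equal(pack$fitness[pack$leaders[1]], min(pack$fitness))
  expect_true(pack$fitness[pack$leaders[1]] <= pack$fitness[pack$leaders[2]])
  expect_true(pack$fitness[pack$leaders[2]] <= pack$fitness[pack$leaders[3]])
  pack2 <- initialize_pack(cfg, sphere)
  expect_identical(pack, pack2)
})

test_that("constant objectives break leader ties by index order", {
  cfg <- gwo_config(3, 1, 10, 0, 1, seed = 0)
  pack <- initialize_pack(cfg, function(z) 7)
  expect_equal(pack$fitness, rep(7, 3))
  expect_equal(pack$leaders, 1:3)
})

test_that("non-finite initial fitness aborts with the offending position", {
  cfg <- gwo_config(3, 1, 10, 0, 1, seed = 1)
  expect_error(initialize_pack(cfg, function(z) NaN), "non-finite objective")
})

test_that("the control parameter follows each variant's linear schedule", {
  std <- gwo_config(3, 1, 100, 0, 1, variant = "standard")
  pap <- gwo_config(3, 1, 100, 0, 1, variant = "paper")
  expect_equal(control_parameter(0, std), 2)
  expect_equal(control_parameter(100, std), 0)
  expect_equal(control_parameter(100, pap), 0)
  expect_equal(control_parameter(50, pap), 0.25)
  expect_equal(control_parameter(0, pap), 0.5)
  mids <- vapply(0:100, control_parameter, 0.0, config = std)
  expect_true(all(diff(mids) < 0))
  expect_error(control_parameter(101, std), "max_iters")
})

test_that("encircling coefficients obey their variant ranges", {
  set.seed(9)
  co <- encircle_coefficients(0, 5, "paper")
  expect_equal(co$x, rep(0, 5))
  co <- encircle_coefficients(0, 5, "standard")
  expect_equal(co$x, rep(0, 5))
  forced <- encircle_coefficients(1, 1, "paper", v1 = 0.5, v2 = 0.5)
  expect_equal(forced$x, 1)   # 2*1*(0.5+0.5) - 1
  expect_equal(forced$y, 1)
  std <- encircle_coefficients(1, 1e5, "standard")
  expect_true(all(std$x >= -1 & std$x <= 1))
  expect_true(all(std$y >= 0 & std$y <= 2))
  pap <- encircle_coefficients(1, 1e5, "paper")
  expect_true(all(pap$x >= -1 & pap$x <= 3))
  expect_true(any(pap$x > 1))   # the widened pulse is actually used
  expect_error(encircle_coefficients(-0.1, 3), "non-negative")
})

test_that("a pack collapsed at the origin is a fixed point of pouncing", {
  cfg <- gwo_config(4, 2, 10, -5, 5, seed = 3)
  pack <- initialize_pack(cfg, sphere)
  pack$positions[] <- 0
  pack$fitness[] <- 0
  pack$leaders <- 1:3
  set.seed(1)
  upd <- pounce_update(pack, m = 1.3, sphere)
  expect_equal(upd$positions, pack$positions)
})

test_that("at m = 0 every wolf moves to the mean of the three leaders", {
  cfg <- gwo_config(5, 2, 10, -10, 10, seed = 3)
  pack <- initialize_pack(cfg, sphere)
  leaders <- pack$positions[pack$leaders, ]
  set.seed(2)
  upd <- pounce_update(pack, m = 0, sphere)
  target <- colMeans(leaders)
  for (i in seq_len(5))
    expect_equal(upd$positions[i, ], target, tolerance = 1e-12)
})

test_that("pouncing matches a by-hand evaluation of the update equations", {
  cfg <- gwo_config(3, 1, 10, -10, 10, seed = 5)
  pack <- initialize_pack(cfg, sphere)
  m <- 0.7
  set.seed(77)
  upd <- pounce_update(pack, m, sphere)
  # independent replication: same RNG stream, formulas written out longhand
  set.seed(77)
  pos <- pack$positions
  expected <- matrix(0, 3, 1)
  acc <- matrix(0, 3, 1)
  for (L in pack$leaders) {
    v1 <- matrix(stats::runif(3), 3, 1)
    v2 <- matrix(stats::runif(3), 3, 1)
    for (i in 1:3) {
      x <- 2 * m * v1[i, 1] - m
      y <- 2 * v2[i, 1]
      E <- abs(y * pos[L, 1] - pos[i, 1])
      acc[i, 1] <- acc[i, 1] + (pos[L, 1] - x * E)
    }
  }
  expected <- pmin(pmax(acc / 3, -10), 10)
  expect_equal(upd$positions, expected, tolerance = 1e-12)
})

test_that("optimization converges on the sphere and keeps its invariants", {
  cfg <- gwo_config(20, 2, 80, -10, 10, seed = 1)
  probe <- list()
  res <- gwo_optimize(sphere, cfg, callback = function(t, pack, best) {
    probe[[length(probe) + 1]] <<- pack$positions
  })
  expect_lt(res$best_fitness, 1e-3)
  expect_equal(res$evaluations, 20 * 81)
  expect_length(res$history, 81)
  expect_true(all(diff(res$history) <= 0))
  for (p in probe) {
    expect_true(all(p >= -10))
    expect_true(all(p <= 10))
  }
  res2 <- gwo_optimize(sphere, cfg)
  expect_identical(res$best_position, res2$best_position)
  expect_identical(res$history, res2$history)
})

test_that("constant objectives give a flat trace and T = 0 returns the best initial wolf", {
  cfg <- gwo_config(5, 2, 15, -1, 1, seed = 6)
  res <- gwo_optimize(function(z) 3.5, cfg)
  expect_equal(res$history, rep(3.5, 16))
  cfg0 <- gwo_config(5, 2, 0, -1, 1, seed = 6)
  pack <- initialize_pack(cfg0, sphere)
  res0 <- gwo_optimize(sphere, cfg0)
  expect_equal(res0$best_fitness, min(pack$fitness))
  expect_equal(res0$best_position,
               pack$positions[which.min(pack$fitness), ])
})

test_that("NaN fitness mid-run becomes +Inf with a warning and the search survives", {
  calls <- new.env(); calls$k <- 0
  tricky <- function(z) {
    calls$k <- calls$k + 1
    if (calls$k > 8 && calls$k <= 12) NaN else sum(z^2)
  }
  cfg <- gwo_config(4, 1, 10, -2, 2, seed = 2)
  expect_warning(res <- gwo_optimize(tricky, cfg), "\\+Inf")
  expect_true(is.finite(res$best_fitness))
  expect_true(all(diff(res$history) <= 0))
})

test_that("both variants coincide when the control parameter hits zero", {
  for (variant in c("standard", "paper")) {
    cfg <- gwo_config(4, 2, 10, -5, 5, variant = variant, seed = 11)
    pack <- initialize_pack(cfg, sphere)
    set.seed(8)
    upd <- pounce_update(pack, 0, sphere)
    if (variant == "standard") first <- upd$positions
    else expect_equal(upd$positions, first, tolerance = 1e-12)
  }
})

test_that("gwo results tidy, glance and write their trace", {
  res <- gwo_optimize(sphere, gwo_config(5, 2, 10, -1, 1, seed = 2))
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("iteration", "best_fitness", "mean_fitness", "m"))
  expect_equal(nrow(td), 11)
  gl <- glance(res)
  expect_equal(gl$evaluations, 55)
  path <- withr::local_tempfile(fileext = ".csv")
  write_gwo_trace(res, path)
  got <- utils::read.csv(path)
  expect_equal(got$best_fitness, td$best_fitness)
  expect_s3_class(autoplot(res), "ggplot")
})
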