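desk_spec <- function() capsnet_spec(conv_filters = 8,
                                     primary_caps_types = 2)

test_that("valid-convolution arithmetic reproduces the printed shape chain", {
  expect_equal(conv_output_side(64, 9, 1), 56)
  expect_equal(conv_output_side(56, 9, 2), 24)
  for (k in c(1, 5, 9)) expect_equal(conv_output_side(k, k, 1), 1)
  expect_error(conv_output_side(8, 9, 1), "exceed")
  spec <- capsnet_spec()
  expect_equal(spec$conv_side, 56)
  expect_equal(spec$grid_side, 24)
  expect_equal(spec$primary_caps_types * spec$primary_caps_dim, 256)
  expect_equal(spec$n_primary, 24 * 24 * 32)
  expect_equal(spec$n_primary, 18432)
})

test_that("squash preserves direction and compresses norms into (0, 1)", {
  expect_equal(squash(c(0, 0, 0)), c(0, 0, 0))
  v <- squash(c(1, 0))
  expect_equal(sqrt(sum(v^2)), 0.5)
  big <- squash(c(100, 0))
  expect_equal(sqrt(sum(big^2)), 10000 / 10001)
  set.seed(1)
  n <- 1e4
  dirs <- matrix(rnorm(n * 8), n, 8)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  norms <- 10^runif(n, -6, 3)
  V <- dirs * norms
  S <- squash(V)
  sn <- sqrt(rowSums(S^2))
  expect_true(all(sn > 0 & sn < 1))
  cosine <- rowSums(S * V) / (sn * norms)
  expect_true(all(abs(cosine - 1) < 1e-6))
})

test_that("routing couplings stay normalized and match a hand-unrolled example", {
  # 2 input capsules, 2 classes, 2-D predictions, 3 iterations
  u_hat <- array(0, c(2, 2, 2))
  u_hat[1, 1, ] <- c(0.8, 0.1);  u_hat[1, 2, ] <- c(-0.2, 0.3)
  u_hat[2, 1, ] <- c(0.7, -0.1); u_hat[2, 2, ] <- c(0.1, 0.4)
  rt <- dynamic_routing(u_hat, iterations = 3)
  for (cc in rt$c_history)
    expect_equal(rowSums(cc), c(1, 1), tolerance = 1e-12)
  # independent scalar unrolling, no shared code with the implementation
  b <- matrix(0, 2, 2)
  sq <- function(x) { n2 <- sum(x^2); x * sqrt(n2) / (1 + n2) }
  for (it in 1:3) {
    cmat <- t(apply(b, 1, function(r) exp(r) / sum(exp(r))))
    s1 <- cmat[1, 1] * u_hat[1, 1, ] + cmat[2, 1] * u_hat[2, 1, ]
    s2 <- cmat[1, 2] * u_hat[1, 2, ] + cmat[2, 2] * u_hat[2, 2, ]
    v1 <- sq(s1); v2 <- sq(s2)
    if (it < 3)
      for (i in 1:2) {
        b[i, 1] <- b[i, 1] + sum(u_hat[i, 1, ] * v1)
        b[i, 2] <- b[i, 2] + sum(u_hat[i, 2, ] * v2)
      }
  }
  expect_equal(rt$v[1, ], v1, tolerance = 1e-10)
  expect_equal(rt$v[2, ], v2, tolerance = 1e-10)
  expect_equal(rt$c, cmat, tolerance = 1e-10)
})

test_that("routing degenerates correctly: one iteration and symmetric votes", {
  u_hat <- array(rnorm(6 * 2 * 4), c(6, 2, 4))
  rt1 <- dynamic_routing(u_hat, iterations = 1)
  expect_equal(rt1$c, matrix(0.5, 6, 2))
  sym <- u_hat
  sym[, 2, ] <- sym[, 1, ]      # identical predictions for both classes
  rt <- dynamic_routing(sym, iterations = 4)
  expect_equal(rt$c, matrix(0.5, 6, 2), tolerance = 1e-12)
  expect_error(dynamic_routing(u_hat, iterations = 0), ">= 1")
})

test_that("the built model honours its architecture spec end to end", {
  spec <- desk_spec()
  model <- build_capsnet(spec, seed = 2)
  x <- withr::with_seed(5, array(runif(64 * 64 * 3), c(64, 64, 3)))
  fw <- gwoscreen:::capsnet_forward(model, x)
  expect_equal(fw$conv_shape, c(56, 56, spec$conv_filters))
  expect_equal(fw$primary_shape,
               c(24, 24, spec$primary_caps_types * spec$primary_caps_dim))
  expect_equal(fw$n_primary, spec$n_primary)
  expect_true(all(fw$class_probabilities >= 0 &
                    fw$class_probabilities < 1))
  # seeded determinism
  model2 <- build_capsnet(spec, seed = 2)
  fw2 <- gwoscreen:::capsnet_forward(model2, x)
  expect_identical(fw$class_probabilities, fw2$class_probabilities)
  expect_error(predict(model, array(0, c(32, 32, 3))), "64x64x3")
})

test_that("margin loss matches its closed forms", {
  mk <- function(n1, n2) list(class_vectors = rbind(c(n1, rep(0, 15)),
                                                    c(n2, rep(0, 15))))
  expect_equal(margin_loss(mk(0.9, 0.1), "glaucoma"), 0)
  expect_equal(margin_loss(mk(0, 0), "glaucoma"), 0.81)
  expect_equal(margin_loss(mk(0.5, 0.5), "glaucoma"),
               0.4^2 + 0.5 * 0.4^2)
})

test_that("training refuses degenerate inputs and is seed-reproducible", {
  spec <- capsnet_spec(input_side = 24, conv_filters = 8,
                       primary_caps_types = 2)
  model <- build_capsnet(spec, seed = 3)
  imgs <- withr::with_seed(4, lapply(1:6, function(i)
    array(runif(24 * 24 * 3), c(24, 24, 3))))
  labs <- rep(c("glaucoma", "normal"), 3)
  expect_error(train_capsnet(model, imgs, rep("normal", 6), epochs = 1),
               "single class")
  fit0 <- train_capsnet(model, imgs, labs, epochs = 0)
  expect_equal(nrow(fit0$trace), 0)
  expect_identical(fit0$model$params, model$params)
  fit1 <- train_capsnet(model, imgs, labs, epochs = 2, batch_size = 2,
                        seed = 9)
  fit2 <- train_capsnet(model, imgs, labs, epochs = 2, batch_size = 2,
                        seed = 9)
  expect_identical(fit1$trace, fit2$trace)
})

test_that("margin loss collapses on linearly separable inputs", {
  # two classes separated by a gross spatial pattern on tiny rasters
  spec <- capsnet_spec(input_side = 24, conv_filters = 8,
                       primary_caps_types = 2)
  model <- build_capsnet(spec, seed = 6)
  set.seed(6)
  imgs <- lapply(1:16, function(i) {
    x <- array(0.2 + rnorm(24 * 24 * 3, sd = 0.05), c(24, 24, 3))
    rows <- if (i %% 2 == 0) 1:12 else 13:24   # bright band top vs bottom
    x[rows, , ] <- x[rows, , ] + 0.6
    pmin(pmax(x, 0), 1)
  })
  labs <- ifelse(seq_len(16) %% 2 == 0, "glaucoma", "normal")
  init_loss <- mean(vapply(seq_len(16), function(i)
    margin_loss(predict(model, imgs[[i]]), labs[i]), 0.0))
  # flips would swap the two bands, so augmentation is off here
  fit <- train_capsnet(model, imgs, labs, epochs = 12, batch_size = 4,
                       learning_rate = 1e-3, seed = 6, patience = Inf,
                       augment = FALSE)
  final_loss <- mean(vapply(seq_len(16), function(i)
    margin_loss(predict(fit$model, imgs[[i]]), labs[i]), 0.0))
  expect_lt(final_loss, 0.1 * init_loss)
  gl <- glance(fit)
  expect_equal(gl$epochs, 12)
})

test_that("batch predictions come back tidily", {
  spec <- capsnet_spec(input_side = 24, conv_filters = 8,
                       primary_caps_types = 2)
  model <- build_capsnet(spec, seed = 1)
  imgs <- withr::with_seed(2, lapply(1:3, function(i)
    array(runif(24 * 24 * 3), c(24, 24, 3))))
  pr <- predict_capsnet(model, imgs, image_id = c("a", "b", "c"))
  expect_named(pr, c("image_id", "p_glaucoma", "p_normal",
                     "predicted_label"))
  expect_equal(nrow(pr), 3)
  expect_true(all(pr$predicted_label %in% c("glaucoma", "normal")))
})
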