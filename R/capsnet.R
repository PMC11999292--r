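caps_classes <- c("glaucoma", "normal")

#' Output side of a valid (unpadded) convolution
#'
#' `floor((in_side - kernel) / stride) + 1`. These are the arithmetic
#' identities behind the capsule network's printed feature-map sizes:
#' a 9x9 kernel at stride 1 maps 64 to 56, and at stride 2 maps 56 to 24.
#'
#' @param in_side Input spatial side.
#' @param kernel Kernel side (must not exceed `in_side`).
#' @param stride Stride (>= 1).
#' @return Integer output side.
#' @export
#' @examples
#' conv_output_side(64, 9, 1) # 56
#' conv_output_side(56, 9, 2) # 24
conv_output_side <- function(in_side, kernel, stride = 1) {
  if (kernel > in_side) stop("`kernel` must not exceed `in_side`")
  if (stride < 1) stop("`stride` must be >= 1")
  as.integer((in_side - kernel) %/% stride + 1)
}

#' Capsule-network architecture specification
#'
#' The default values reproduce the printed architecture: a 64x64x3 input,
#' a 9x9 convolution to 256 feature maps (giving 56x56x256), a primary
#' capsule layer of 32 capsule types of 8 dimensions on a 24x24 grid
#' (9x9 kernel, stride 2, so 32 x 8 = 256 channels), and dynamic routing to
#' 2 class capsules ("glaucoma", "normal") of 16 dimensions. A desk-scale
#' profile for CPU training shrinks `conv_filters` and
#' `primary_caps_types`; the spatial arithmetic is unchanged.
#'
#' @param input_side,input_channels Input raster geometry.
#' @param conv_kernel,conv_filters,conv_stride First convolution.
#' @param primary_kernel,primary_stride Primary-capsule convolution.
#' @param primary_caps_types,primary_caps_dim Number of capsule types and
#'   their vector dimension (the primary convolution emits
#'   `types * dim` channels).
#' @param class_caps,class_caps_dim Class capsules and their dimension.
#' @param routing_iters Routing-by-agreement iterations (>= 1).
#' @return An object of class `capsnet_spec` with derived fields
#'   `conv_side`, `grid_side`, `n_primary`.
#' @export
capsnet_spec <- function(input_side = 64, input_channels = 3,
                         conv_kernel = 9, conv_filters = 256,
                         conv_stride = 1,
                         primary_kernel = 9, primary_stride = 2,
                         primary_caps_types = 32, primary_caps_dim = 8,
                         class_caps = 2, class_caps_dim = 16,
                         routing_iters = 3) {
  stopifnot(routing_iters >= 1, class_caps >= 2,
            primary_caps_types >= 1, primary_caps_dim >= 1)
  conv_side <- conv_output_side(input_side, conv_kernel, conv_stride)
  grid_side <- conv_output_side(conv_side, primary_kernel, primary_stride)
  structure(
    list(input_side = as.integer(input_side),
         input_channels = as.integer(input_channels),
         conv_kernel = as.integer(conv_kernel),
         conv_filters = as.integer(conv_filters),
         conv_stride = as.integer(conv_stride),
         primary_kernel = as.integer(primary_kernel),
         primary_stride = as.integer(primary_stride),
         primary_caps_types = as.integer(primary_caps_types),
         primary_caps_dim = as.integer(primary_caps_dim),
         class_caps = as.integer(class_caps),
         class_caps_dim = as.integer(class_caps_dim),
         routing_iters = as.integer(routing_iters),
         conv_side = conv_side, grid_side = grid_side,
         n_primary = grid_side^2 * as.integer(primary_caps_types)),
    class = "capsnet_spec")
}

#' Squashing nonlinearity for capsule vectors
#'
#' Maps each vector `v` to `(||v||^2 / (1 + ||v||^2)) * v / ||v||`: the
#' direction is preserved and the norm is compressed strictly below 1, so a
#' capsule's length can be read as a probability of presence. The zero
#' vector maps to itself.
#'
#' @param v A numeric vector, or a matrix whose rows are squashed
#'   independently.
#' @return Same shape as `v`.
#' @export
#' @examples
#' sqrt(sum(squash(c(1, 0))^2)) # 0.5
squash <- function(v) {
  if (is.matrix(v)) {
    n <- sqrt(rowSums(v^2))
    f <- n / (1 + n^2)
    v * f
  } else {
    n <- sqrt(sum(v^2))
    v * (n / (1 + n^2))
  }
}

#' Dynamic routing-by-agreement between capsule layers
#'
#' Routing logits `b` start at zero. Each iteration computes coupling
#' coefficients `c = softmax(b)` over the class axis (so each input
#' capsule's couplings sum to 1), the weighted votes
#' `s_j = sum_i c_ij u_hat_ij`, the squashed outputs `v_j = squash(s_j)`,
#' and the agreement update `b_ij <- b_ij + u_hat_ij . v_j`.
#'
#' @param u_hat Prediction array `n_input x n_class x dim`.
#' @param iterations Number of routing iterations (>= 1).
#' @return A list: `v` (`n_class x dim` output capsules), `c` (final
#'   couplings, rows sum to 1), `s` (final pre-squash votes), and
#'   `c_history` (couplings at every iteration).
#' @export
dynamic_routing <- function(u_hat, iterations = 3) {
  if (iterations < 1) stop("`iterations` must be >= 1")
  stopifnot(length(dim(u_hat)) == 3)
  n <- dim(u_hat)[1]; J <- dim(u_hat)[2]; D <- dim(u_hat)[3]
  b <- matrix(0, n, J)
  c_hist <- vector("list", iterations)
  v <- matrix(0, J, D); s <- matrix(0, J, D); cc <- NULL
  for (it in seq_len(iterations)) {
    e <- exp(b - apply(b, 1, max))
    cc <- e / rowSums(e)
    c_hist[[it]] <- cc
    for (j in seq_len(J)) {
      uj <- matrix(u_hat[, j, ], ncol = D)
      s[j, ] <- colSums(cc[, j] * uj)
    }
    v <- squash(s)
    if (it < iterations)
      for (j in seq_len(J)) {
        uj <- matrix(u_hat[, j, ], ncol = D)
        b[, j] <- b[, j] + uj %*% v[j, ]
      }
  }
  list(v = v, c = cc, s = s, c_history = c_hist)
}

#' Build a capsule-network classifier
#'
#' Composes convolution, primary capsules (convolution + reshape to
#' `grid^2 * types` capsules of `primary_caps_dim` dimensions + squash),
#' dynamic routing, and the class capsules whose norms are the class
#' probabilities. Weights are He-initialized (convolutions) and Gaussian
#' (routing transforms) from `seed`.
#'
#' @param spec A [capsnet_spec()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `capsnet_model`.
#' @export
build_capsnet <- function(spec = capsnet_spec(), seed = 1L) {
  stopifnot(inherits(spec, "capsnet_spec"))
  pd <- spec$primary_caps_types * spec$primary_caps_dim
  params <- withr::with_seed(seed, {
    list(
      "conv1.W" = he_conv(spec$conv_kernel, spec$input_channels,
                          spec$conv_filters),
      "conv1.b" = numeric(spec$conv_filters),
      "primary.W" = he_conv(spec$primary_kernel, spec$conv_filters, pd),
      "primary.b" = numeric(pd),
      # routing transforms scaled so the initial vote sums s_j have norm
      # O(1): with ~n_primary random votes the sum grows like sqrt(n), so
      # sd ~ 1/sqrt(n) keeps the class capsules out of squash saturation
      "Wcaps" = array(stats::rnorm(spec$n_primary * spec$class_caps *
                                     spec$primary_caps_dim *
                                     spec$class_caps_dim,
                                   sd = 1 / sqrt(spec$n_primary)),
                      dim = c(spec$n_primary, spec$class_caps,
                              spec$primary_caps_dim, spec$class_caps_dim)))
  })
  structure(list(params = params, spec = spec, classes = caps_classes,
                 adam = NULL),
            class = "capsnet_model")
}

#' @export
print.capsnet_model <- function(x, ...) {
  s <- x$spec
  cat("<capsnet_model> ", s$input_side, "x", s$input_side, "x",
      s$input_channels, " -> conv ", s$conv_side, "x", s$conv_side, "x",
      s$conv_filters, " -> ", s$n_primary, " primary caps (",
      s$primary_caps_types, " x ", s$primary_caps_dim, "-D on ",
      s$grid_side, "x", s$grid_side, ") -> ", s$class_caps, " x ",
      s$class_caps_dim, "-D class caps\n", sep = "")
  invisible(x)
}

# primary conv output (grid x grid x types*dim) -> capsule matrix n x dim,
# capsule order = (position within grid, then type).
pc_to_caps <- function(pc, spec) {
  g <- spec$grid_side; ty <- spec$primary_caps_types
  D <- spec$primary_caps_dim
  A <- matrix(pc, nrow = g * g)        # spatial x (types*dim)
  U <- matrix(0, g * g * ty, D)
  for (t in seq_len(ty))
    U[((t - 1) * g * g + 1):(t * g * g), ] <-
      A[, ((t - 1) * D + 1):(t * D)]
  U
}

caps_to_pc <- function(U, spec) {
  g <- spec$grid_side; ty <- spec$primary_caps_types
  D <- spec$primary_caps_dim
  A <- matrix(0, g * g, ty * D)
  for (t in seq_len(ty))
    A[, ((t - 1) * D + 1):(t * D)] <-
      U[((t - 1) * g * g + 1):(t * g * g), ]
  array(A, dim = c(g, g, ty * D))
}

capsnet_forward <- function(model, x, train = FALSE) {
  spec <- model$spec
  if (length(dim(x)) != 3 ||
      !all(dim(x) == c(spec$input_side, spec$input_side,
                       spec$input_channels)))
    stop("expected a ", spec$input_side, "x", spec$input_side, "x",
         spec$input_channels, " input, got ",
         paste(dim(x), collapse = "x"))
  # per-image standardization: removes the global brightness/contrast
  # nuisance (the archive-style jitter) so intensity bands are comparable
  # across images and the cup/disc contrast carries the signal
  s <- stats::sd(x)
  x <- (x - mean(x)) / (if (s > 0) s else 1)
  tp <- tape_new(model$params, train = train)
  id <- t_input(tp, x)
  id <- t_relu(tp, t_conv(tp, id, "conv1", stride = spec$conv_stride))
  conv_shape <- dim(tp$vals[[id]])
  pc_id <- t_conv(tp, id, "primary", stride = spec$primary_stride)
  pc <- tp$vals[[pc_id]]
  U0 <- pc_to_caps(pc, spec)
  u <- squash(U0)
  W <- model$params$Wcaps
  J <- spec$class_caps; Do <- spec$class_caps_dim
  Di <- spec$primary_caps_dim
  u_hat <- array(0, dim = c(nrow(u), J, Do))
  for (j in seq_len(J))
    for (dd in seq_len(Do))
      u_hat[, j, dd] <- rowSums(u * W[, j, , dd])
  rt <- dynamic_routing(u_hat, spec$routing_iters)
  probs <- sqrt(rowSums(rt$v^2))
  names(probs) <- model$classes
  list(class_vectors = rt$v,
       class_probabilities = probs,
       predicted_label = model$classes[which.max(probs)],
       conv_shape = conv_shape, primary_shape = dim(pc),
       n_primary = nrow(u),
       tp = tp, pc_id = pc_id, U0 = U0, u = u, u_hat = u_hat, routing = rt)
}

#' Classify an image with a capsule network
#'
#' @param object A [build_capsnet()] model.
#' @param image `side x side x channels` array matching the model's
#'   architecture spec, intensities
#'   in `[0, 1]`.
#' @param ... Unused.
#' @return A list (`caps_output`): `class_vectors` (2 x 16),
#'   `class_probabilities` (named norms, each in `[0, 1)`),
#'   `predicted_label`.
#' @export
predict.capsnet_model <- function(object, image, ...) {
  fw <- capsnet_forward(object, image, train = FALSE)
  structure(fw[c("class_vectors", "class_probabilities",
                 "predicted_label")],
            class = "caps_output")
}

#' Margin loss on class-capsule norms
#'
#' `L = sum_k [T_k max(0, m+ - ||v_k||)^2 +
#' lambda (1 - T_k) max(0, ||v_k|| - m-)^2]` with `m+ = 0.9`, `m- = 0.1`,
#' `lambda = 0.5`: the present class is pushed above `m+`, absent classes
#' below `m-`.
#'
#' @param output A `caps_output` (or any list with `class_vectors`).
#' @param label `"glaucoma"` or `"normal"`.
#' @param m_pos,m_neg,lambda Margin-loss constants.
#' @return A single non-negative number.
#' @export
margin_loss <- function(output, label, m_pos = 0.9, m_neg = 0.1,
                        lambda = 0.5) {
  stopifnot(label %in% caps_classes)
  v <- output$class_vectors
  n <- sqrt(rowSums(v^2))
  Tk <- as.numeric(caps_classes == label)
  sum(Tk * pmax(0, m_pos - n)^2 + lambda * (1 - Tk) * pmax(0, n - m_neg)^2)
}

margin_loss_grad <- function(v, label, m_pos = 0.9, m_neg = 0.1,
                             lambda = 0.5) {
  n <- sqrt(rowSums(v^2))
  Tk <- as.numeric(caps_classes == label)
  dldn <- -2 * Tk * pmax(0, m_pos - n) +
    2 * lambda * (1 - Tk) * pmax(0, n - m_neg)
  dv <- v * ifelse(n > 1e-12, dldn / n, 0)
  dv
}

# Jacobian-vector product of the squash applied row-wise: for each row s
# with norm nr, J = f(nr) I + (f'(nr)/nr) s s^T, f(n) = n/(1+n^2).
# One of the 8 dihedral transforms of an H x W x C raster (label-preserving
# augmentation for roughly isotropic disc crops).
dihedral <- function(x, k) {
  if (k >= 4) x <- aperm(x, c(2, 1, 3))
  k <- k %% 4
  if (k %in% c(1, 3)) x <- x[rev(seq_len(dim(x)[1])), , , drop = FALSE]
  if (k %in% c(2, 3)) x <- x[, rev(seq_len(dim(x)[2])), , drop = FALSE]
  x
}

squash_vjp <- function(S, dV) {
  nr <- sqrt(rowSums(S^2))
  f <- nr / (1 + nr^2)
  fp <- (1 - nr^2) / (1 + nr^2)^2
  coef <- ifelse(nr > 1e-8, fp / nr, 0) * rowSums(S * dV)
  dV * f + S * coef
}

#' Train the capsule-network classifier
#'
#' Adam on the margin loss with mini-batches, a validation holdout, and
#' early stopping on validation loss (best parameters restored). Gradients
#' flow through the final routing state with the coupling coefficients held
#' fixed. Zero epochs returns an empty trace and the model unchanged.
#'
#' @param model A [build_capsnet()] model.
#' @param images List of input arrays (or a 4-D array).
#' @param labels Character vector of `"glaucoma"` / `"normal"`, aligned
#'   with `images`; both classes must be present.
#' @param epochs Maximum epochs.
#' @param batch_size Mini-batch size (gradients averaged per batch).
#' @param learning_rate Adam learning rate.
#' @param seed Seed for the holdout split, shuffling and augmentation.
#' @param patience Early-stopping patience in epochs (`Inf` disables).
#' @param val_fraction Fraction held out for validation.
#' @param augment Apply a random dihedral transform (flip/transpose) to each
#'   training sample every epoch; disc crops are close to isotropic so all
#'   eight are label-preserving.
#' @return An object of class `caps_fit`: trained `model`, `trace` tibble
#'   (`epoch`, `train_loss`, `val_loss`, `val_accuracy`), `best_epoch`.
#' @export
train_capsnet <- function(model, images, labels, epochs = 15,
                          batch_size = 8, learning_rate = 1e-3,
                          seed = 1L, patience = 10, val_fraction = 0.2,
                          augment = TRUE) {
  stopifnot(inherits(model, "capsnet_model"))
  images <- as_sample_list(images)
  labels <- as.character(labels)
  stopifnot(length(images) == length(labels),
            all(labels %in% caps_classes))
  if (length(unique(labels)) < 2)
    stop("training set contains a single class")
  if (epochs == 0)
    return(structure(list(model = model,
                          trace = tibble::tibble(epoch = integer(),
                                                 train_loss = numeric(),
                                                 val_loss = numeric(),
                                                 val_accuracy = numeric()),
                          best_epoch = 0L),
                     class = "caps_fit"))
  n <- length(images)
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
      ord <- sample(tr_idx)
      batches <- split(ord, ceiling(seq_along(ord) / batch_size))
      tr_loss <- 0
      for (bt in batches) {
        gacc <- NULL
        for (i in bt) {
          mdl$params <- params
          xi <- if (augment) dihedral(images[[i]], sample(0:7, 1)) else
            images[[i]]
          gi <- caps_sample_grads(mdl, xi, labels[i])
          tr_loss <- tr_loss + gi$loss
          gacc <- if (is.null(gacc)) gi$grads else
            purrr::map2(gacc, gi$grads[names(gacc)], `+`)
        }
        gacc <- lapply(gacc, function(g) g / length(bt))
        st <- adam_step(params, gacc, adam, learning_rate)
        params <- st$params; adam <- st$state
      }
      tr_loss <- tr_loss / length(tr_idx)
      mdl$params <- params
      val_loss <- 0; correct <- 0
      for (i in val_idx) {
        fw <- capsnet_forward(mdl, images[[i]])
        val_loss <- val_loss + margin_loss(fw, labels[i])
        correct <- correct + (fw$predicted_label == labels[i])
      }
      val_loss <- val_loss / n_val
      rows[[ep]] <- tibble::tibble(epoch = ep, train_loss = tr_loss,
                                   val_loss = val_loss,
                                   val_accuracy = correct / n_val)
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
            class = "caps_fit")
}

# Margin-loss gradients for one sample: through the class capsules, the
# final routing state (couplings fixed), the primary squash, and the conv
# stack on the tape.
caps_sample_grads <- function(model, x, label) {
  spec <- model$spec
  fw <- capsnet_forward(model, x, train = TRUE)
  loss <- margin_loss(fw, label)
  dv <- margin_loss_grad(fw$routing$v, label)
  ds <- squash_vjp(fw$routing$s, dv)          # J x Do
  cc <- fw$routing$c
  J <- spec$class_caps; Di <- spec$primary_caps_dim
  Do <- spec$class_caps_dim
  u <- fw$u; W <- model$params$Wcaps
  dW <- array(0, dim = dim(W))
  du <- matrix(0, nrow(u), Di)
  for (j in seq_len(J)) {
    for (dd in seq_len(Do)) {
      dhat <- cc[, j] * ds[j, dd]             # n-vector
      for (di in seq_len(Di)) {
        dW[, j, di, dd] <- u[, di] * dhat
        du[, di] <- du[, di] + W[, j, di, dd] * dhat
      }
    }
  }
  dU0 <- squash_vjp(fw$U0, du)
  dpc <- caps_to_pc(dU0, spec)
  grads <- tape_backward(fw$tp, fw$pc_id, dpc)
  grads$Wcaps <- dW
  list(loss = loss, grads = grads)
}

#' @export
print.caps_fit <- function(x, ...) {
  if (nrow(x$trace) == 0) {
    cat("<caps_fit> untrained (0 epochs)\n")
  } else {
    last <- x$trace[nrow(x$trace), ]
    cat("<caps_fit> ", nrow(x$trace), " epochs (best at ", x$best_epoch,
        "), val accuracy ", round(last$val_accuracy, 3), "\n", sep = "")
  }
  invisible(x)
}

#' @export
tidy.caps_fit <- function(x, ...) x$trace

#' @export
glance.caps_fit <- function(x, ...) {
  if (nrow(x$trace) == 0)
    return(tibble::tibble(epochs = 0L, best_epoch = 0L,
                          val_loss = NA_real_, val_accuracy = NA_real_))
  best <- x$trace[x$trace$epoch == x$best_epoch, ]
  tibble::tibble(epochs = nrow(x$trace), best_epoch = x$best_epoch,
                 val_loss = best$val_loss,
                 val_accuracy = best$val_accuracy)
}

#' Training-curve plot for a capsule-network fit
#'
#' @param object A `caps_fit`.
#' @param ... Unused.
#' @export
autoplot.caps_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$trace, -"epoch",
                            names_to = "series", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = NULL, title = "CapsNet training")
}

#' Batch predictions as a tibble
#'
#' @param model A `capsnet_model`.
#' @param images List of input arrays (or a 4-D array).
#' @param image_id Optional identifiers (defaults to the index).
#' @param tta Average the class-capsule norms over the 8 dihedral
#'   transforms of each image (deterministic test-time augmentation,
#'   matching the training-time augmentation).
#' @return A tibble: `image_id`, `p_glaucoma`, `p_normal`,
#'   `predicted_label`.
#' @export
predict_capsnet <- function(model, images, image_id = NULL, tta = FALSE) {
  images <- as_sample_list(images)
  image_id <- image_id %||% seq_along(images)
  purrr::map2_dfr(images, image_id, function(x, id) {
    probs <- if (tta) {
      rowMeans(vapply(0:7, function(k)
        predict(model, dihedral(x, k))$class_probabilities,
        numeric(2)))
    } else {
      predict(model, x)$class_probabilities
    }
    tibble::tibble(image_id = id,
                   p_glaucoma = probs[["glaucoma"]],
                   p_normal = probs[["normal"]],
                   predicted_label = model$classes[which.max(probs)])
  })
}
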