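# Minimal reverse-mode training engine shared by the UNet++ segmenter and
# the capsule-network classifier. Tensors are plain H x W x C arrays;
# convolutions are im2col (C++) + BLAS matrix products; a small tape records
# the forward graph so concatenations and skip re-use backpropagate with
# correct gradient accumulation.

#' @useDynLib gwoscreen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
NULL

he_conv <- function(k, cin, f) {
  array(stats::rnorm(k * k * cin * f, sd = sqrt(2 / (k * k * cin))),
        dim = c(k, k, cin, f))
}

tape_new <- function(params, train = FALSE) {
  tp <- new.env(parent = emptyenv())
  tp$params <- params
  tp$train <- train
  tp$vals <- list()
  tp$steps <- list()
  tp$n <- 0L
  tp
}

t_put <- function(tp, val, step = NULL) {
  tp$n <- tp$n + 1L
  tp$vals[[tp$n]] <- val
  if (!is.null(step)) {
    step$out <- tp$n
    tp$steps[[length(tp$steps) + 1L]] <- step
  }
  tp$n
}

t_input <- function(tp, x) t_put(tp, x)

# Convolution with weights tp$params[[paste0(name,".W")]] (k x k x Cin x F)
# and bias ".b". pad is symmetric zero padding.
t_conv <- function(tp, id, name, stride = 1L, pad = 0L) {
  force(id)
  x <- tp$vals[[id]]
  W <- tp$params[[paste0(name, ".W")]]
  b <- tp$params[[paste0(name, ".b")]]
  k <- dim(W)[1]; f <- dim(W)[4]
  cols <- nn_im2col(x, k, stride, pad)
  Wm <- matrix(W, ncol = f)
  out_mat <- crossprod(Wm, cols) + b        # F x nloc, bias recycled by row
  oH <- (dim(x)[1] + 2 * pad - k) %/% stride + 1
  oW <- (dim(x)[2] + 2 * pad - k) %/% stride + 1
  out <- array(t(out_mat), dim = c(oH, oW, f))
  t_put(tp, out, list(op = "conv", inputs = id, name = name,
                      cache = list(cols = cols, dims = dim(x), k = k,
                                   stride = stride, pad = pad, f = f)))
}

t_relu <- function(tp, id) {
  force(id)
  x <- tp$vals[[id]]
  t_put(tp, pmax(x, 0), list(op = "relu", inputs = id,
                             cache = list(mask = x > 0)))
}

t_sigmoid <- function(tp, id) {
  force(id)
  out <- 1 / (1 + exp(-tp$vals[[id]]))
  t_put(tp, out, list(op = "sigmoid", inputs = id, cache = list(out = out)))
}

t_pool <- function(tp, id) {
  force(id)
  x <- tp$vals[[id]]
  r <- nn_maxpool2(x)
  t_put(tp, r$out, list(op = "pool", inputs = id,
                        cache = list(idx = r$idx, H = dim(x)[1],
                                     W = dim(x)[2])))
}

t_up <- function(tp, id) {
  force(id)
  t_put(tp, nn_upsample2(tp$vals[[id]]),
        list(op = "up", inputs = id, cache = NULL))
}

t_concat <- function(tp, ids) {
  force(ids)
  xs <- tp$vals[ids]
  chans <- vapply(xs, function(a) dim(a)[3], 0L)
  d <- dim(xs[[1]])
  out <- array(unlist(xs, use.names = FALSE),
               dim = c(d[1], d[2], sum(chans)))
  t_put(tp, out, list(op = "concat", inputs = ids,
                      cache = list(chans = chans)))
}

t_dropout <- function(tp, id, p) {
  force(id)
  x <- tp$vals[[id]]
  if (!tp$train || p <= 0) return(id)
  mask <- array(stats::rbinom(length(x), 1, 1 - p) / (1 - p), dim = dim(x))
  t_put(tp, x * mask, list(op = "dropout", inputs = id,
                           cache = list(mask = mask)))
}

# Backpropagate dL/d(vals[[out_id]]); returns named parameter gradients.
tape_backward <- function(tp, out_id, dout) {
  g <- vector("list", tp$n)
  g[[out_id]] <- dout
  pg <- list()
  add_g <- function(lst, id, val) {
    lst[[id]] <- if (is.null(lst[[id]])) val else lst[[id]] + val
    lst
  }
  for (s in rev(tp$steps)) {
    go <- g[[s$out]]
    if (is.null(go)) next
    switch(s$op,
      conv = {
        cc <- s$cache
        dout_mat <- matrix(go, ncol = cc$f)
        dW <- array(cc$cols %*% dout_mat,
                    dim = dim(tp$params[[paste0(s$name, ".W")]]))
        db <- colSums(dout_mat)
        pg <- add_g(pg, paste0(s$name, ".W"), dW)
        pg <- add_g(pg, paste0(s$name, ".b"), db)
        Wm <- matrix(tp$params[[paste0(s$name, ".W")]], ncol = cc$f)
        dcols <- Wm %*% t(dout_mat)
        g <- add_g(g, s$inputs,
                   nn_col2im(dcols, cc$dims[1], cc$dims[2], cc$dims[3],
                             cc$k, cc$stride, cc$pad))
      },
      relu = {
        g <- add_g(g, s$inputs, go * s$cache$mask)
      },
      sigmoid = {
        o <- s$cache$out
        g <- add_g(g, s$inputs, go * o * (1 - o))
      },
      pool = {
        g <- add_g(g, s$inputs,
                   nn_maxpool2_bwd(go, s$cache$idx, s$cache$H, s$cache$W))
      },
      up = {
        g <- add_g(g, s$inputs, nn_upsample2_bwd(go))
      },
      concat = {
        off <- 0L
        for (i in seq_along(s$inputs)) {
          ch <- s$cache$chans[i]
          g <- add_g(g, s$inputs[i], go[, , off + seq_len(ch), drop = FALSE])
          off <- off + ch
        }
      },
      dropout = {
        g <- add_g(g, s$inputs, go * s$cache$mask)
      },
      mean_heads = {
        for (id in s$inputs) g <- add_g(g, id, go / s$cache$k)
      })
    g[s$out] <- list(NULL)   # free memory without shifting list indices
  }
  pg
}

adam_new <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    gr <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

param_checksum <- function(params) {
  sum(vapply(params, function(p) sum(as.numeric(p)), 0.0))
}
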