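#' Configure a Grey Wolf Optimization run
#'
#' Grey Wolf Optimization (GWO) is a population metaheuristic in which the
#' three best solutions found so far -- the alpha, beta and gamma leaders --
#' attract the remaining pack through stochastic "encircling" and "pouncing"
#' moves whose step size decays linearly over the run. This constructor
#' validates and freezes every knob of a run: the pack size, the bounded
#' continuous search box, the iteration budget, and which coefficient variant
#' drives the encircling step.
#'
#' Two coefficient variants are available. `variant = "standard"` uses the
#' canonical schedule `m = 2 (1 - t/T)` and coefficient `x = 2 m v1 - m`
#' (so `x` spans `[-m, m]`). `variant = "paper"` uses the halved schedule
#' `m = (1 - t/T) / 2` with `x = 2 m (v1 + v2) - m` (spanning `[-m, 3m]`),
#' a wider, asymmetric exploration pulse. Both collapse to the same
#' deterministic update at `m = 0`.
#'
#' @param n_wolves Number of search agents; at least 3 so the three leaders
#'   exist.
#' @param dim Dimension of the search space.
#' @param max_iters Iteration budget `T` (>= 0; 0 returns the best initial
#'   wolf).
#' @param lower_bounds,upper_bounds Numeric vectors of length `dim` (scalars
#'   are recycled) with `lower_bounds < upper_bounds` elementwise.
#' @param variant `"standard"` or `"paper"` coefficient rules (see Details).
#' @param seed Integer seed controlling every random draw of the run.
#' @param leader_combine How the three leader-guided candidate positions are
#'   merged; only `"mean"` (their arithmetic mean) is defined.
#' @return An object of class `gwo_config`.
#' @seealso [gwo_optimize()]
#' @export
#' @examples
#' cfg <- gwo_config(n_wolves = 12, dim = 2, max_iters = 50,
#'                   lower_bounds = -5, upper_bounds = 5, seed = 1)
gwo_config <- function(n_wolves, dim, max_iters,
                       lower_bounds, upper_bounds,
                       variant = c("standard", "paper"),
                       seed = 1L,
                       leader_combine = "mean") {
  variant <- match.arg(variant)
  stopifnot(is.numeric(n_wolves), length(n_wolves) == 1, n_wolves >= 3,
            is.numeric(dim), length(dim) == 1, dim >= 1,
            is.numeric(max_iters), length(max_iters) == 1, max_iters >= 0)
  if (!identical(leader_combine, "mean"))
    stop("`leader_combine` must be \"mean\"")
  lower_bounds <- rep_len(as.numeric(lower_bounds), dim)
  upper_bounds <- rep_len(as.numeric(upper_bounds), dim)
  if (!all(is.finite(lower_bounds)) || !all(is.finite(upper_bounds)))
    stop("bounds must be finite")
  if (!all(lower_bounds < upper_bounds))
    stop("`lower_bounds` must be strictly below `upper_bounds` elementwise")
  structure(
    list(n_wolves = as.integer(n_wolves), dim = as.integer(dim),
         max_iters = as.integer(max_iters),
         lower_bounds = lower_bounds, upper_bounds = upper_bounds,
         variant = variant, seed = as.integer(seed),
         leader_combine = leader_combine),
    class = "gwo_config")
}

#' Linearly decaying control parameter of the encircling step
#'
#' Returns the scalar `m` that scales the stochastic encircling coefficients
#' at iteration `t` of a `T`-iteration run. `variant = "standard"` decays
#' from 2 to 0 (`m = 2 (1 - t/T)`); `variant = "paper"` from 1/2 to 0
#' (`m = (1 - t/T) / 2`). Both are linear and non-increasing in `t`.
#'
#' @param iteration Current iteration `t`, `0 <= t <= max_iters`.
#' @param config A [gwo_config()].
#' @return A single non-negative number.
#' @export
#' @examples
#' cfg <- gwo_config(3, 1, 100, 0, 1)
#' control_parameter(0, cfg)   # 2
#' control_parameter(100, cfg) # 0
control_parameter <- function(iteration, config) {
  stopifnot(inherits(config, "gwo_config"))
  t <- iteration
  T <- config$max_iters
  if (t < 0 || t > T) stop("`iteration` must lie in [0, max_iters]")
  frac <- if (T == 0) 1 else 1 - t / T
  switch(config$variant,
         standard = 2 * frac,
         paper    = 0.5 * frac)
}

#' Draw the stochastic encircling coefficients
#'
#' Draws the per-dimension coefficient vectors `x` and `y` used by the
#' pouncing update. With `v1, v2 ~ U(0, 1)` i.i.d. per dimension,
#' `variant = "standard"` sets `x = 2 m v1 - m` (range `[-m, m]`) and
#' `variant = "paper"` sets `x = 2 m (v1 + v2) - m` (range `[-m, 3m]`);
#' both set `y = 2 v2` (range `[0, 2]`). At `m = 0`, `x` is exactly 0 for
#' either variant.
#'
#' @param m Non-negative control parameter from [control_parameter()].
#' @param dim Number of dimensions to draw.
#' @param variant `"standard"` or `"paper"`.
#' @param v1,v2 Optional forced uniform draws (numeric vectors of length
#'   `dim`), used by tests; by default drawn from the current RNG stream.
#' @return A list with numeric vectors `x` and `y` of length `dim`.
#' @export
encircle_coefficients <- function(m, dim, variant = c("standard", "paper"),
                                  v1 = NULL, v2 = NULL) {
  variant <- match.arg(variant)
  if (m < 0) stop("`m` must be non-negative")
  if (is.null(v1)) v1 <- stats::runif(dim)
  if (is.null(v2)) v2 <- stats::runif(dim)
  x <- switch(variant,
              standard = 2 * m * v1 - m,
              paper    = 2 * m * (v1 + v2) - m)
  list(x = x, y = 2 * v2)
}

rank_leaders <- function(fitness) {
  order(fitness, seq_along(fitness))[1:3]
}

#' Initialize a wolf pack on a bounded box
#'
#' Draws `n_wolves` positions uniformly inside the search box from the
#' configured seed, evaluates the objective at each, and ranks the alpha,
#' beta and gamma leaders by ascending fitness (ties broken by index, lower
#' index wins).
#'
#' @param config A [gwo_config()].
#' @param objective Function of a length-`dim` numeric vector returning one
#'   finite number (minimized).
#' @return An object of class `wolf_pack`: positions (`n_wolves x dim`),
#'   `fitness`, `leaders` (indices of alpha, beta, gamma), `iteration`.
#' @export
initialize_pack <- function(config, objective) {
  stopifnot(inherits(config, "gwo_config"))
  n <- config$n_wolves; d <- config$dim
  positions <- withr::with_seed(config$seed, {
    matrix(stats::runif(n * d), n, d)
  })
  positions <- sweep(positions, 2, config$upper_bounds - config$lower_bounds, `*`)
  positions <- sweep(positions, 2, config$lower_bounds, `+`)
  fitness <- vapply(seq_len(n), function(i) objective(positions[i, ]), 0.0)
  bad <- which(!is.finite(fitness))
  if (length(bad))
    stop("non-finite objective at initial position [",
         paste(signif(positions[bad[1], ], 6), collapse = ", "), "]")
  structure(
    list(positions = positions, fitness = fitness, iteration = 0L,
         leaders = rank_leaders(fitness), config = config),
    class = "wolf_pack")
}

#' One pouncing (exploitation) update of the whole pack
#'
#' For every wolf and each leader L in (alpha, beta, gamma), fresh coefficient
#' draws give the unsigned distance `E_L = |y * GW_L - GW_i|` and the
#' candidate `GW_L - x * E_L`; the wolf moves to the arithmetic mean of its
#' three candidates, hard-clipped to the search box. Leaders are re-ranked
#' after the move.
#'
#' @param pack A `wolf_pack`.
#' @param m Control parameter for this iteration.
#' @param objective Objective used to re-evaluate fitness after the move.
#'   Non-finite values are replaced by `+Inf` with a warning.
#' @return The updated `wolf_pack`.
#' @export
pounce_update <- function(pack, m, objective) {
  stopifnot(inherits(pack, "wolf_pack"))
  cfg <- pack$config
  n <- cfg$n_wolves; d <- cfg$dim
  pos <- pack$positions
  acc <- matrix(0, n, d)
  for (L in pack$leaders) {
    leader <- matrix(pos[L, ], n, d, byrow = TRUE)
    v1 <- matrix(stats::runif(n * d), n, d)
    v2 <- matrix(stats::runif(n * d), n, d)
    x <- if (cfg$variant == "paper") 2 * m * (v1 + v2) - m else 2 * m * v1 - m
    y <- 2 * v2
    E <- abs(y * leader - pos)
    acc <- acc + (leader - x * E)
  }
  newpos <- acc / 3
  newpos <- pmin(pmax(newpos,
                      matrix(cfg$lower_bounds, n, d, byrow = TRUE)),
                 matrix(cfg$upper_bounds, n, d, byrow = TRUE))
  fitness <- vapply(seq_len(n), function(i) objective(newpos[i, ]), 0.0)
  if (any(!is.finite(fitness))) {
    warning("non-finite fitness replaced by +Inf for ",
            sum(!is.finite(fitness)), " wolf/wolves")
    fitness[!is.finite(fitness)] <- Inf
  }
  pack$positions <- newpos
  pack$fitness <- fitness
  pack$iteration <- pack$iteration + 1L
  pack$leaders <- rank_leaders(fitness)
  pack
}

#' Run Grey Wolf Optimization on a scalar objective
#'
#' Full minimization loop: seeded initialization, then `max_iters` rounds of
#' leader ranking and pouncing updates under the linearly decaying control
#' parameter. The returned history is the best-so-far fitness after
#' initialization and after each iteration, so it is non-increasing by
#' construction; total objective evaluations are `n_wolves * (max_iters + 1)`.
#'
#' @param objective Function of a length-`dim` vector returning one number.
#' @param config A [gwo_config()].
#' @param callback Optional function called after each iteration as
#'   `callback(iteration, pack, best_fitness)`.
#' @return An object of class `gwo_result` with `best_position`,
#'   `best_fitness`, `history` (length `max_iters + 1`), `evaluations`, and a
#'   per-iteration `trace` tibble (`iteration`, `best_fitness`,
#'   `mean_fitness`, `m`).
#' @export
#' @examples
#' sphere <- function(z) sum(z^2)
#' cfg <- gwo_config(20, 2, 60, -5, 5, seed = 7)
#' res <- gwo_optimize(sphere, cfg)
#' res$best_fitness
gwo_optimize <- function(objective, config, callback = NULL) {
  stopifnot(inherits(config, "gwo_config"))
  pack <- initialize_pack(config, objective)
  best_i <- pack$leaders[1]
  best_fit <- pack$fitness[best_i]
  best_pos <- pack$positions[best_i, ]
  T <- config$max_iters
  history <- numeric(T + 1)
  history[1] <- best_fit
  trace <- vector("list", T + 1)
  trace[[1]] <- tibble::tibble(iteration = 0L, best_fitness = best_fit,
                               mean_fitness = mean(pack$fitness),
                               m = control_parameter(0, config))
  if (T > 0) {
    withr::with_seed(config$seed + 1L, {
      for (t in seq_len(T)) {
        m <- control_parameter(t, config)
        pack <- pounce_update(pack, m, objective)
        it_best <- pack$leaders[1]
        if (pack$fitness[it_best] < best_fit) {
          best_fit <- pack$fitness[it_best]
          best_pos <- pack$positions[it_best, ]
        }
        history[t + 1] <- best_fit
        fin <- pack$fitness[is.finite(pack$fitness)]
        trace[[t + 1]] <- tibble::tibble(
          iteration = t, best_fitness = best_fit,
          mean_fitness = if (length(fin)) mean(fin) else NA_real_, m = m)
        if (!is.null(callback)) callback(t, pack, best_fit)
      }
    })
  }
  structure(
    list(best_position = best_pos, best_fitness = best_fit,
         history = history,
         evaluations = config$n_wolves * (T + 1L),
         trace = dplyr::bind_rows(trace), config = config),
    class = "gwo_result")
}

#' @export
print.gwo_result <- function(x, ...) {
  cat("<gwo_result> ", x$config$variant, " variant, ",
      x$config$n_wolves, " wolves, ", x$config$max_iters, " iterations\n",
      "  best fitness: ", format(x$best_fitness), "\n",
      "  best position: [", paste(signif(x$best_position, 5), collapse = ", "),
      "]\n", sep = "")
  invisible(x)
}

#' Tidy the per-iteration trace of a GWO run
#'
#' @param x A `gwo_result`.
#' @param ... Unused.
#' @return A tibble with columns `iteration`, `best_fitness`, `mean_fitness`,
#'   `m`.
#' @export
tidy.gwo_result <- function(x, ...) x$trace

#' One-row summary of a GWO run
#'
#' @param x A `gwo_result`.
#' @param ... Unused.
#' @export
glance.gwo_result <- function(x, ...) {
  tibble::tibble(best_fitness = x$best_fitness,
                 iterations = x$config$max_iters,
                 n_wolves = x$config$n_wolves,
                 evaluations = x$evaluations,
                 variant = x$config$variant)
}

#' Convergence plot for a GWO run
#'
#' @param object A `gwo_result`.
#' @param ... Unused.
#' @return A ggplot of best-so-far fitness against iteration (log10 y scale
#'   when all fitness values are positive).
#' @export
autoplot.gwo_result <- function(object, ...) {
  df <- object$trace
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration,
                                        y = .data$best_fitness)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "iteration", y = "best fitness",
                  title = "GWO convergence")
  if (all(df$best_fitness > 0)) p <- p + ggplot2::scale_y_log10()
  p
}

#' Write a GWO trace to CSV
#'
#' Columns: `iteration`, `best_fitness`, `mean_fitness`, `m`.
#'
#' @param result A `gwo_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_gwo_trace <- function(result, path) {
  utils::write.csv(result$trace, path, row.names = FALSE)
  invisible(path)
}
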