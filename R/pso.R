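#' Particle swarm optimizer configuration
#'
#' Hyperparameters of the global-best particle swarm used to tune the ELM
#' input layer. The velocity update is
#' `v <- w*v + c1*r1*(pbest - x) + c2*r2*(gbest - x)` (clamped to `v_max`),
#' and positions move as `x <- x + m*v` (clipped to the search bounds),
#' where `m` is the velocity-position coefficient. The inertia weight `w`
#' may be a constant or a `(start, end)` pair interpolated linearly across
#' the iteration budget (the "0.9~0.3" convention).
#'
#' @param pop particle count, `>= 2`.
#' @param w inertia weight: a single value or a length-2 `(start, end)`
#'   schedule.
#' @param c1,c2 cognitive and social learning factors, `> 0`.
#' @param m velocity-position coefficient, `> 0`.
#' @param iterations iteration budget, `>= 1` (default 100).
#' @param seed RNG seed.
#' @param bounds length-2 per-dimension search interval (default `[-1, 1]`).
#' @param v_max_frac velocity clamp as a fraction of the bound width
#'   (default 0.5).
#' @return An object of class `pso_config`.
#' @export
pso_config <- function(pop = 50L, w = c(0.9, 0.3), c1 = 1.65, c2 = 2.8,
                       m = 0.2, iterations = 100L, seed = 1L,
                       bounds = c(-1, 1), v_max_frac = 0.5) {
  pop <- as.integer(pop)
  iterations <- as.integer(iterations)
  if (pop < 2L) stop("`pop` must be >= 2", call. = FALSE)
  if (iterations < 1L) stop("`iterations` must be >= 1", call. = FALSE)
  if (!length(w) %in% 1:2 || any(!is.finite(w))) {
    stop("`w` must be a constant or a (start, end) pair", call. = FALSE)
  }
  assert_scalar_number(c1, "c1", lower = 0, strict_lower = TRUE)
  assert_scalar_number(c2, "c2", lower = 0, strict_lower = TRUE)
  assert_scalar_number(m, "m", lower = 0, strict_lower = TRUE)
  stopifnot(length(bounds) == 2L, bounds[1] < bounds[2])
  assert_scalar_number(v_max_frac, "v_max_frac", lower = 0,
                       strict_lower = TRUE)
  structure(
    list(pop = pop, w = as.numeric(w), c1 = c1, c2 = c2, m = m,
         iterations = iterations, seed = as.integer(seed),
         bounds = as.numeric(bounds), v_max_frac = v_max_frac),
    class = "pso_config"
  )
}

#' Inertia weight at a given iteration
#'
#' Linear interpolation between the schedule endpoints: iteration 1 gets
#' `w_start`, iteration `total` gets `w_end` exactly.
#'
#' @param w constant or `(start, end)` pair.
#' @param iter current iteration (1-based).
#' @param total total iterations.
#' @return Inertia weight.
#' @examples
#' inertia_at(c(0.9, 0.3), 1, 100)    # 0.9
#' inertia_at(c(0.9, 0.3), 100, 100)  # 0.3
#' @export
inertia_at <- function(w, iter, total) {
  if (length(w) == 1L) return(w)
  if (iter <= 1L || total == 1L) return(w[1L])
  if (iter >= total) return(w[2L])   # endpoint exact, no round-off
  w[1L] + (w[2L] - w[1L]) * (iter - 1) / (total - 1)
}

#' Minimize a function with a global-best particle swarm
#'
#' @param fitness function taking a numeric vector of length `dim` and
#'   returning a finite scalar (lower is better). A non-finite value aborts
#'   with an error naming the offending particle.
#' @param dim search-space dimension.
#' @param cfg a [pso_config()].
#' @param init optional matrix of initial positions (up to `pop` rows);
#'   remaining particles are drawn uniformly inside the bounds.
#' @return An object of class `pso_result`: `position`, `fitness`, `trace`
#'   (global-best fitness after initialisation and after each iteration;
#'   non-increasing), and `config`.
#' @examples
#' res <- pso_minimize(function(x) sum(x^2), 2,
#'                     pso_config(pop = 20, iterations = 50, seed = 1,
#'                                bounds = c(-5, 5)))
#' res$fitness
#' @export
pso_minimize <- function(fitness, dim, cfg, init = NULL) {
  stopifnot(is.function(fitness), inherits(cfg, "pso_config"))
  dim <- as.integer(dim)
  if (dim < 1L) stop("`dim` must be >= 1", call. = FALSE)
  lo <- cfg$bounds[1L]; hi <- cfg$bounds[2L]
  v_max <- cfg$v_max_frac * (hi - lo)

  eval_all <- function(X) {
    vapply(seq_len(nrow(X)), function(i) {
      f <- fitness(X[i, ])
      if (!is.numeric(f) || length(f) != 1L || !is.finite(f)) {
        stop(sprintf("non-finite fitness for particle %d", i), call. = FALSE)
      }
      f
    }, numeric(1))
  }

  local_seed(cfg$seed, {
    X <- matrix(stats::runif(cfg$pop * dim, lo, hi), cfg$pop, dim)
    if (!is.null(init)) {
      init <- as.matrix(init)
      stopifnot(ncol(init) == dim)
      k <- min(nrow(init), cfg$pop)
      X[seq_len(k), ] <- pmin(pmax(init[seq_len(k), , drop = FALSE], lo), hi)
    }
    V <- matrix(0, cfg$pop, dim)
    fit <- eval_all(X)
    pbest <- X
    pbest_fit <- fit
    g <- which.min(fit)
    gbest <- X[g, ]
    gbest_fit <- fit[g]
    trace <- numeric(cfg$iterations + 1L)
    trace[1L] <- gbest_fit

    for (t in seq_len(cfg$iterations)) {
      w_t <- inertia_at(cfg$w, t, cfg$iterations)
      r1 <- matrix(stats::runif(cfg$pop * dim), cfg$pop, dim)
      r2 <- matrix(stats::runif(cfg$pop * dim), cfg$pop, dim)
      V <- w_t * V + cfg$c1 * r1 * (pbest - X) +
        cfg$c2 * r2 * (matrix(gbest, cfg$pop, dim, byrow = TRUE) - X)
      V <- pmin(pmax(V, -v_max), v_max)
      X <- pmin(pmax(X + cfg$m * V, lo), hi)
      fit <- eval_all(X)
      improved <- fit < pbest_fit
      pbest[improved, ] <- X[improved, , drop = FALSE]
      pbest_fit[improved] <- fit[improved]
      g <- which.min(pbest_fit)
      if (pbest_fit[g] < gbest_fit) {
        gbest_fit <- pbest_fit[g]
        gbest <- pbest[g, ]
      }
      trace[t + 1L] <- gbest_fit
    }
    structure(
      list(position = gbest, fitness = gbest_fit, trace = trace,
           config = cfg),
      class = "pso_result"
    )
  })
}

#' @export
print.pso_result <- function(x, ...) {
  cat(sprintf("<pso_result> dim %d, final fitness %.6g after %d iterations\n",
              length(x$position), x$fitness, length(x$trace) - 1L))
  invisible(x)
}
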