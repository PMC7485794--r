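sphere <- function(x) sum(x^2)

test_that("inertia schedules interpolate linearly between their endpoints", {
  w <- c(0.9, 0.3)
  expect_equal(inertia_at(w, 1, 100), 0.9)
  expect_equal(inertia_at(w, 100, 100), 0.3)
  expect_equal(inertia_at(w, 51, 101), 0.6)    # midpoint
  expect_equal(inertia_at(0.7, 13, 100), 0.7)  # constant schedule
})

test_that("a swarm initialized at the optimum stays there", {
  cfg <- pso_config(pop = 5, iterations = 10, seed = 1, bounds = c(-2, 2))
  init <- matrix(0, 5, 3)
  res <- pso_minimize(sphere, 3, cfg, init = init)
  expect_equal(res$fitness, 0)
  expect_true(all(res$trace == 0))
})

test_that("the global best never worsens", {
  cfg <- pso_config(pop = 12, w = c(0.9, 0.3), iterations = 60, seed = 3,
                    bounds = c(-5, 5), m = 1)
  res <- pso_minimize(function(x) sum((x - 1)^2) + 0.5, 4, cfg)
  expect_true(all(diff(res$trace) <= 0))
  expect_equal(res$fitness, res$trace[length(res$trace)])
})

test_that("the swarm solves the 2-D sphere to high precision", {
  cfg <- pso_config(pop = 20, w = c(0.9, 0.3), c1 = 1.65, c2 = 2.8, m = 1,
                    iterations = 100, seed = 7, bounds = c(-5, 5))
  res <- pso_minimize(sphere, 2, cfg)
  expect_lt(res$fitness, 1e-3)
})

test_that("non-finite fitness aborts naming the particle", {
  cfg <- pso_config(pop = 3, iterations = 2, seed = 1)
  expect_error(pso_minimize(function(x) NaN, 2, cfg), "particle 1")
})

test_that("swarm runs are reproducible under a fixed seed", {
  cfg <- pso_config(pop = 10, iterations = 20, seed = 11, bounds = c(-3, 3))
  r1 <- pso_minimize(sphere, 3, cfg)
  r2 <- pso_minimize(sphere, 3, cfg)
  expect_identical(r1$position, r2$position)
  expect_identical(r1$trace, r2$trace)
})

test_that("config validation rejects bad hyperparameters", {
  expect_error(pso_config(pop = 1), "pop")
  expect_error(pso_config(iterations = 0), "iterations")
  expect_error(pso_config(c1 = -1), "c1")
  expect_error(pso_config(m = 0), "m")
  expect_error(pso_config(w = c(0.9, 0.3, 0.1)), "w")
})

test_that("a degenerate one-particle swarm refits a warm-started ELM unchanged", {
  set.seed(21)
  X <- matrix(runif(40), 20, 2); y <- rnorm(20)
  Xv <- matrix(runif(10), 5, 2); yv <- rnorm(5)
  base <- elm_fit(X, y, hidden_count = 4, seed = 2)
  cfg <- pso_config(pop = 2, iterations = 1, seed = 3, m = 1e-12)
  warm <- pso_elm_fit(X, y, Xv, yv, hidden_count = 4, cfg = cfg,
                      init = rbind(encode_elm_layer(base),
                                   encode_elm_layer(base)))
  expect_equal(warm$input_weights, base$input_weights, tolerance = 1e-9)
  expect_equal(warm$output_weights, base$output_weights, tolerance = 1e-6)
})

test_that("PSO-ELM is reproducible and reports its own fitness", {
  set.seed(22)
  X <- matrix(runif(60), 30, 2); y <- 5 + 3 * X[, 1] + rnorm(30, 0, 0.1)
  Xv <- matrix(runif(20), 10, 2); yv <- 5 + 3 * Xv[, 1] + rnorm(10, 0, 0.1)
  cfg <- pso_config(pop = 8, iterations = 15, seed = 5)
  m1 <- pso_elm_fit(X, y, Xv, yv, hidden_count = 5, cfg = cfg)
  m2 <- pso_elm_fit(X, y, Xv, yv, hidden_count = 5, cfg = cfg)
  expect_identical(m1$input_weights, m2$input_weights)
  expect_identical(m1$output_weights, m2$output_weights)
  # the recorded fitness is the validation RMSE of the returned model
  expect_equal(m1$val_rmse, rmse(yv, elm_predict(m1, Xv)), tolerance = 1e-12)
  expect_equal(m1$val_rmse, m1$trace[length(m1$trace)])
})
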