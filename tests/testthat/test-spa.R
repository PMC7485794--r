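test_that("the first SPA pick is the largest-norm column", {
  X <- cbind(c(1, 1, 0), c(3, 0, 0), c(0, 0, 2))
  expect_equal(spa_select(X, 1)[1], 2L, ignore_attr = TRUE)
})

test_that("orthogonal columns are selected in decreasing norm order", {
  X <- diag(c(2, 5, 1, 4))
  expect_equal(as.integer(spa_select(X, 4)), c(2L, 4L, 1L, 3L))
})

test_that("an exactly collinear duplicate is never selected second", {
  x1 <- c(1, 2, 3, 4)
  X <- cbind(x1, x1, c(0, 0, 1, -1))
  sel <- as.integer(spa_select(X, 2))
  expect_equal(sel[1], 1L)       # ties at max norm resolve to the first
  expect_equal(sel[2], 3L)       # duplicate has zero residual
})

test_that("selection matches the independent projection oracle on random matrices", {
  for (seed in 1:12) {
    set.seed(seed)
    X <- matrix(rnorm(6 * 8), 6, 8)
    expect_equal(as.integer(spa_select(X, 4)), spa_oracle(X, 4),
                 info = paste("seed", seed))
  }
})

test_that("residual norms never increase across iterations", {
  set.seed(99)
  X <- matrix(rnorm(10 * 12), 10, 12)
  sel <- spa_select(X, 6)
  hist <- attr(sel, "history")
  for (k in 2:length(hist)) {
    shared <- intersect(names(hist[[k]]), names(hist[[k - 1]]))
    expect_true(all(hist[[k]][shared] <= hist[[k - 1]][shared] + 1e-12))
  }
})

test_that("selection is invariant to positive rescaling of the matrix", {
  set.seed(17)
  X <- matrix(rnorm(8 * 10), 8, 10)
  expect_equal(as.integer(spa_select(X, 5)),
               as.integer(spa_select(0.003 * X, 5)))
})

test_that("rank-deficient input stops early with a warning", {
  x1 <- c(1, 0, 0); x2 <- c(0, 1, 0)
  X <- cbind(x1, x2, x1 + x2)   # rank 2
  expect_warning(sel <- spa_select(X, 3), "floor")
  expect_equal(length(sel), 2L)
  expect_error(spa_select(X, 5), "N")
})

test_that("MLR refinement recovers an exact linear subset at minimal size", {
  set.seed(8)
  n <- 40
  vals <- matrix(runif(n * 5, 0, 1), n, 5)
  chl <- 10 + 30 * vals[, 1] - 20 * vals[, 3]
  s <- tiny_set(vals, chl = chl)
  ref <- mlr_refine(s, candidate_indices = 1:5, seed = 2)
  expect_equal(sort(ref$refined_indices), c(1L, 3L))
  expect_lt(ref$refined_rmse, 1e-8)
})

test_that("a single candidate is returned as-is", {
  set.seed(9)
  s <- tiny_set(matrix(runif(30), 10, 3), chl = runif(10, 2, 99))
  ref <- mlr_refine(s, candidate_indices = 2L, seed = 1)
  expect_equal(ref$refined_indices, 2L)
  expect_equal(nrow(ref$subset_table), 1L)
})

test_that("refinement equals a brute-force CV enumeration with lm()", {
  set.seed(30)
  n <- 36
  vals <- matrix(runif(n * 4, 0, 1), n, 4)
  chl <- 5 + 40 * vals[, 2] + 15 * vals[, 4]^2 + rnorm(n, 0, 2)
  s <- tiny_set(vals, chl = chl)
  folds <- rep(1:5, length.out = n)
  ref <- mlr_refine(s, candidate_indices = 1:4, folds = folds)

  # independent route: lm() per subset, pooled held-out RMSE
  oracle_rmse <- function(cols) {
    err <- numeric(0)
    for (f in 1:5) {
      d_tr <- data.frame(y = chl[folds != f], vals[folds != f, cols, drop = FALSE])
      d_te <- data.frame(vals[folds == f, cols, drop = FALSE])
      names(d_tr)[-1] <- names(d_te) <- paste0("v", cols)
      fit <- lm(y ~ ., data = d_tr)
      err <- c(err, chl[folds == f] - predict(fit, d_te))
    }
    sqrt(mean(err^2))
  }
  subsets <- unlist(lapply(1:4, function(k)
    combn(4, k, simplify = FALSE)), recursive = FALSE)
  rmses <- vapply(subsets, oracle_rmse, numeric(1))
  best <- subsets[[which.min(rmses)]]
  expect_equal(sort(ref$refined_indices), best)
  expect_equal(ref$refined_rmse, min(rmses), tolerance = 1e-10)
})

test_that("candidate count limits are enforced", {
  s <- tiny_set(matrix(runif(40), 10, 4), chl = runif(10))
  expect_error(mlr_refine(s, candidate_indices = integer(0)), "1 and 15")
  expect_error(mlr_refine(s, candidate_indices = c(1L, 1L)), "distinct")
})
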