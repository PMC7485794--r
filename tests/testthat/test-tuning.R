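test_that("the L25 design is balanced and pairwise orthogonal", {
  des <- build_l25_design()
  runs <- des$runs
  # every level of every factor in exactly 5 runs
  for (j in 1:5) expect_true(all(table(runs[, j]) == 5L))
  # every ordered factor pair sees all 25 level combinations once
  for (j in 1:4) for (k in (j + 1):5) {
    tab <- table(runs[, j], runs[, k])
    expect_true(all(dim(tab) == c(5L, 5L)) && all(tab == 1L))
  }
  # first factor in blocks of five constant levels
  expect_equal(runs[, "pop"], rep(1:5, each = 5), ignore_attr = TRUE)
})

test_that("the canonical generator reproduces the published run table", {
  des <- build_l25_design()
  ref <- reference_orthogonal_runs()
  lv <- default_pso_levels()
  fmt <- function(v) paste(v, collapse = "~")
  for (r in 1:25) {
    expect_equal(lv$pop[[des$runs[r, "pop"]]], ref$pop[r])
    expect_equal(fmt(lv$w[[des$runs[r, "w"]]]), as.character(ref$w[r]))
    expect_equal(lv$c1[[des$runs[r, "c1"]]], ref$c1[r])
    expect_equal(lv$c2[[des$runs[r, "c2"]]], ref$c2[r])
    expect_equal(lv$m[[des$runs[r, "m"]]], ref$m[r])
  }
})

test_that("marginal sums of the reference runs match the published analysis", {
  des <- build_l25_design()
  r2 <- reference_orthogonal_runs()$r2
  mt <- marginal_analysis(des, r2)
  expect_equal(mt$W["level1", "pop"], 3.782)
  expect_equal(mt$W["level2", "pop"], 3.820)
  expect_equal(mt$W["level1", "c1"], 3.716)
  expect_equal(mt$W["level3", "w"], 3.653)
  # conservation: every factor column partitions the same 25 runs
  expect_equal(unname(colSums(mt$W)), rep(sum(r2), 5))
  # selected working parameters; note the marginal argmax of the c2 column
  # is its level 3 (sum 3.838 at c2 = 1.65 vs 3.737 at c2 = 2.8)
  expect_equal(mt$best_values$pop, 50L)
  expect_equal(mt$best_values$w, c(0.9, 0.3))
  expect_equal(mt$best_values$c1, 1.65)
  expect_equal(mt$best_values$c2, 1.65)
  expect_equal(mt$best_values$m, 0.2)
})

test_that("marginal analysis is equivariant under level relabeling", {
  des <- build_l25_design()
  set.seed(31)
  r2 <- runif(25, 0.6, 0.8)
  mt <- marginal_analysis(des, r2)
  # swap levels 1 and 2 of factor 3 in the design
  des2 <- des
  col <- des2$runs[, 3]
  des2$runs[, 3] <- ifelse(col == 1L, 2L, ifelse(col == 2L, 1L, col))
  mt2 <- marginal_analysis(des2, r2)
  expect_equal(mt2$W[1:2, 3], unname(mt$W[2:1, 3]), ignore_attr = TRUE)
  expect_equal(mt2$W[, -3], mt$W[, -3])
})

test_that("constant responses tie every factor with a warning", {
  des <- build_l25_design()
  warns <- capture_warnings(mt <- marginal_analysis(des, rep(0.7, 25)))
  expect_length(warns, 5)          # one tie per factor
  expect_match(warns, "tie", all = TRUE)
  expect_true(all(mt$W == 5 * 0.7))
  expect_true(all(mt$best_level == 1L))
  expect_error(marginal_analysis(des, rep(0.7, 24)), "25")
})

test_that("the orthogonal experiment is reproducible and its optimum is sane", {
  set.seed(41)
  n <- 40
  X <- matrix(runif(2 * n), n, 2)
  y <- 20 + 30 * X[, 1] - 10 * X[, 2]^2 + rnorm(n, 0, 1)
  tr <- 1:30; va <- 31:40
  lv <- default_pso_levels()
  lv$pop <- list(3L, 4L, 5L, 6L, 7L)   # desk-scale swarm sizes
  des <- build_l25_design(lv)
  r2a <- run_orthogonal_experiment(X[tr, ], y[tr], X[va, ], y[va], des,
                                   hidden_count = 5, iterations = 3, seed = 13)
  r2b <- run_orthogonal_experiment(X[tr, ], y[tr], X[va, ], y[va], des,
                                   hidden_count = 5, iterations = 3, seed = 13)
  expect_identical(r2a, r2b)
  expect_equal(length(r2a), 25L)

  mt <- marginal_analysis(des, r2a)
  bv <- mt$best_values
  cfg <- pso_config(pop = bv$pop, w = bv$w, c1 = bv$c1, c2 = bv$c2, m = bv$m,
                    iterations = 3, seed = derive_seed(13, "confirm"))
  model <- pso_elm_fit(X[tr, ], y[tr], X[va, ], y[va], hidden_count = 5,
                       cfg = cfg)
  r2_opt <- r2_score(y[va], elm_predict(model, X[va, ]))
  expect_gte(r2_opt, median(r2a) - 0.05)
})
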