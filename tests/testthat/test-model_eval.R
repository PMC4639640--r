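test_that("stratified folds preserve class proportions and determinism", {
  y <- c(rep(1L, 20), rep(0L, 200))
  f <- stratified_folds(y, 10, seed = 5)
  for (k in 1:10) {
    expect_equal(sum(y[f == k] == 1), 2)
    expect_equal(sum(y[f == k] == 0), 20)
  }
  expect_identical(f, stratified_folds(y, 10, seed = 5))
  expect_false(identical(f, stratified_folds(y, 10, seed = 6)))
  expect_error(stratified_folds(c(rep(1, 5), rep(0, 50)), 10), "at least")
})

test_that("AUC equals the pair-counting oracle", {
  expect_equal(roc_auc(c(3, 4, 1, 2), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(0:1, 5))$auc, 0.5)

  sc <- c(0.9, 0.8, 0.8, 0.4, 0.3, 0.1)
  lb <- c(1, 0, 1, 1, 0, 0)
  expect_equal(roc_auc(sc, lb)$auc, auc_oracle(sc, lb), tolerance = 1e-12)

  for (seed in 1:10) {
    d <- withr::with_seed(seed, {
      n <- sample(10:50, 1)
      list(sc = round(runif(n), 1), lb = rbinom(n, 1, 0.5))
    })
    if (length(unique(d$lb)) < 2) next
    expect_equal(roc_auc(d$sc, d$lb)$auc, auc_oracle(d$sc, d$lb),
                 tolerance = 1e-12)
  }
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("ROC endpoints and monotonicity", {
  d <- withr::with_seed(2, list(sc = runif(30), lb = rbinom(30, 1, 0.4)))
  roc <- roc_auc(d$sc, d$lb)$roc
  expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1); expect_equal(roc$tpr[nrow(roc)], 1)
  expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
})

test_that("confusion metrics reproduce the closed-form values", {
  # TP=3, FP=1, TN=5, FN=1
  pred <- c(rep(TRUE, 4), rep(FALSE, 6))
  lab <- c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0)
  m <- confusion_metrics(pred, lab)
  expect_equal(m$MCC, 14 / 24)
  expect_equal(m$Acc, 0.8)
  expect_equal(m$Pre, 0.75)
  expect_equal(m$Sn, 0.75)
  expect_equal(m$Sp, 5 / 6)
})

test_that("stringency thresholds maximize Sn subject to Sp", {
  sc <- c(0.95, 0.9, 0.8, 0.7, 0.6, 0.5, 0.4, 0.3, 0.2, 0.1)
  lb <- c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0)
  m <- metrics_at_stringency(sc, lb, 0.80)
  # Sp > 0.8 requires at most 1 FP among 6 negatives
  expect_gt(m$Sp, 0.80)
  # perfect classifier: all metrics 1 at any level
  mp <- metrics_at_stringency(c(1, 1, 0, 0), c(1, 1, 0, 0), 0.95)
  expect_equal(unlist(mp[c("Sn", "Sp", "Acc", "Pre", "MCC")]),
               c(Sn = 1, Sp = 1, Acc = 1, Pre = 1, MCC = 1))
  # everything rejected: Sn = 0 and the MCC 0-denominator guard
  mz <- metrics_at_stringency(rep(0.5, 10), rep(0:1, 5), 0.9)
  expect_equal(mz$Sn, 0)
  expect_equal(mz$MCC, 0)
  expect_error(metrics_at_stringency(sc, lb, 1), "no threshold")
})

test_that("Acc decomposes as (Sn*P + Sp*N)/(P+N) at every threshold", {
  d <- withr::with_seed(8, list(sc = round(runif(40), 2),
                                lb = rbinom(40, 1, 0.3)))
  P <- sum(d$lb == 1); N <- sum(d$lb == 0)
  for (t in c(Inf, sort(unique(d$sc), decreasing = TRUE))) {
    m <- confusion_metrics(d$sc >= t, d$lb)
    expect_equal(m$Acc, (m$Sn * P + m$Sp * N) / (P + N), tolerance = 1e-12)
  }
})

test_that("grid search returns the AUC-maximizing pair with the tie rule", {
  d <- withr::with_seed(5, {
    y <- rep(0:1, each = 20)
    X <- matrix(rnorm(40 * 2, mean = rep(y * 2, 2)), 40, 2)
    list(X = X, y = y)
  })
  # single-cell grid: no choice
  g1 <- grid_search(d$X, d$y, cost_grid = 2, gamma_grid = 0.5,
                    n_folds = 5, seed = 1)
  expect_equal(c(g1$cost, g1$gamma), c(2, 0.5))
  # chosen pair attains the grid maximum; ties resolve to smallest pair
  g <- grid_search(d$X, d$y, cost_grid = c(0.5, 4), gamma_grid = c(0.1, 1),
                   n_folds = 5, seed = 1)
  expect_equal(g$auc, max(g$grid$auc))
  top <- g$grid[g$grid$auc == g$auc, ]
  top <- top[order(top$cost, top$gamma), ]
  expect_equal(c(g$cost, g$gamma), c(top$cost[1], top$gamma[1]))
})

test_that("forward selection tracks the argmax of its own trace", {
  d <- withr::with_seed(6, {
    y <- rep(0:1, each = 25)
    Xs <- matrix(rbinom(50 * 4, 1, 0.5), 50, 4)       # uninformative baseline
    Xg <- cbind(y, matrix(rbinom(50 * 2, 1, 0.5), 50, 2))
    list(y = y, Xs = Xs, Xg = Xg)
  })
  tr <- forward_select(d$Xs, d$Xg, d$y, n_folds = 5, seed = 1,
                       cost_grid = c(1, 8), gamma_grid = c(0.05, 0.5))
  expect_length(tr$auc_at_step, ncol(d$Xg) + 1)
  expect_equal(tr$optimal_auc, max(tr$auc_at_step))
  expect_gte(tr$optimal_auc, tr$auc_at_step[1])
  # the oracle GO feature (rank 1) lifts AUC to ~1 at step 1
  expect_gt(tr$auc_at_step[2], 0.95)
})

test_that("evaluate_cv scores each instance once and is seed-stable", {
  d <- withr::with_seed(7, {
    y <- rep(0:1, each = 30)
    X <- matrix(rnorm(60 * 3, mean = rep(y, 3)), 60, 3)
    list(X = X, y = y)
  })
  r1 <- evaluate_cv(d$X, d$y, cost = 1, gamma = 0.3, n_folds = 5, seed = 2)
  expect_length(r1$scores, 60)
  expect_true(all(c("high", "medium", "low") %in% r1$levels$level))
  expect_true(all(diff(r1$levels$Sp) <= 0 + 1e-12) ||
                all(r1$levels$Sp >= c(0.95, 0.90, 0.85)))
  r2 <- evaluate_cv(d$X, d$y, cost = 1, gamma = 0.3, n_folds = 5, seed = 2)
  expect_identical(r1$scores, r2$scores)
  expect_identical(r1$levels, r2$levels)
})
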