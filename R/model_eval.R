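#' Seeded stratified fold assignment
#'
#' Each class is shuffled with the seeded generator and dealt round-robin
#' to folds, so per-fold class proportions match the global proportions
#' within one instance.
#'
#' @param labels 0/1 vector.
#' @param n_folds Number of folds (default 10).
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1:n_folds`.
#' @export
stratified_folds <- function(labels, n_folds = 10L, seed = 1L) {
  labels <- as.integer(labels)
  counts <- table(labels)
  if (any(counts < n_folds))
    stop("each class needs at least ", n_folds, " members for ", n_folds,
         "-fold stratification")
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cl in names(counts)) {
      idx <- which(labels == as.integer(cl))
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  folds
}

#' ROC curve and AUC by the rank statistic
#'
#' AUC is the Mann-Whitney statistic U / (n1 * n0) with mid-rank tie
#' handling; the ROC curve is the unique-threshold sweep.
#'
#' @param scores Numeric scores (larger = more positive).
#' @param labels 0/1 vector, both classes present.
#' @return List with `auc` and `roc` (data frame threshold, fpr, tpr).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes required for ROC")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  roc <- data.frame(
    threshold = thr,
    fpr = vapply(thr, function(t) sum(scores >= t & labels == 0L) / n0, 0),
    tpr = vapply(thr, function(t) sum(scores >= t & labels == 1L) / n1, 0))
  list(auc = auc, roc = roc)
}

#' Confusion-matrix metrics at a specificity stringency level
#'
#' Scans the descending unique scores and picks the threshold maximizing
#' sensitivity subject to specificity strictly above `sp_level`
#' (predicted positive means score >= threshold). MCC is defined as 0
#' when any factor of its denominator is 0.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 vector.
#' @param sp_level Specificity floor (e.g. 0.95, 0.90, 0.85).
#' @return List with threshold, TP/FP/TN/FN, and Acc, Sn, Sp, Pre, MCC.
#' @export
metrics_at_stringency <- function(scores, labels, sp_level) {
  labels <- as.integer(labels)
  if (sp_level >= 1) stop("no threshold can attain Sp > ", sp_level)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  best <- NULL
  for (t in thr) {
    m <- confusion_metrics(scores >= t, labels)
    if (m$Sp > sp_level && (is.null(best) || m$Sn > best$Sn)) {
      m$threshold <- t
      best <- m
    }
  }
  best
}

#' Metrics from a predicted-positive indicator
#' @param pred Logical/0-1 predicted-positive vector.
#' @param labels 0/1 truth vector.
#' @return List with TP, FP, TN, FN, Acc, Sn, Sp, Pre, MCC.
#' @export
confusion_metrics <- function(pred, labels) {
  pred <- as.logical(pred); labels <- as.integer(labels)
  TP <- sum(pred & labels == 1L); FP <- sum(pred & labels == 0L)
  FN <- sum(!pred & labels == 1L); TN <- sum(!pred & labels == 0L)
  den <- (TP + FN) * (TP + FP) * (TN + FN) * (TN + FP)
  list(TP = TP, FP = FP, TN = TN, FN = FN,
       Acc = (TN + TP) / (TN + TP + FN + FP),
       Sn = if (TP + FN > 0) TP / (TP + FN) else 0,
       Sp = if (TN + FP > 0) TN / (TN + FP) else 0,
       Pre = if (TP + FP > 0) TP / (TP + FP) else 0,
       MCC = if (den > 0) (TP * TN - FP * FN) / sqrt(den) else 0)
}

# Pooled out-of-fold probability scores for one feature subset.
.cv_scores <- function(X, labels, folds, cost, gamma, weight_ratio = NULL,
                       weight_mode = "positive") {
  scores <- numeric(length(labels))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    fit <- train_svm(X[tr, , drop = FALSE], labels[tr], cost = cost,
                     gamma = gamma, weight_ratio = weight_ratio,
                     weight_mode = weight_mode)
    scores[!tr] <- predict(fit, X[!tr, , drop = FALSE], type = "probability")
  }
  scores
}

#' Grid search for SVM cost and gamma by pooled CV AUC
#'
#' Default grids follow common RBF-SVM practice: cost 2^-5..2^15 and
#' gamma 2^-15..2^3, both in steps of 2^2. Ties resolve toward the
#' smaller cost, then the smaller gamma.
#'
#' @param features Feature matrix.
#' @param labels 0/1 vector.
#' @param cost_grid,gamma_grid Candidate values.
#' @param folds Fold assignment (see [stratified_folds()]), or `NULL` to
#'   build one from `seed`.
#' @param seed Seed used when `folds` is `NULL`.
#' @param n_folds Folds built when `folds` is `NULL` (default 10).
#' @param weight_mode Class weighting mode passed to [train_svm()].
#' @return List with `cost`, `gamma`, `auc`, and the full `grid` data frame.
#' @export
grid_search <- function(features, labels,
                        cost_grid = 2^seq(-5, 15, by = 2),
                        gamma_grid = 2^seq(-15, 3, by = 2),
                        folds = NULL, seed = 1L, n_folds = 10L,
                        weight_mode = "positive") {
  stopifnot(length(cost_grid) >= 1L, length(gamma_grid) >= 1L)
  X <- as.matrix(features)
  if (is.null(folds)) folds <- stratified_folds(labels, n_folds, seed)
  grid <- expand.grid(cost = sort(cost_grid), gamma = sort(gamma_grid))
  grid$auc <- vapply(seq_len(nrow(grid)), function(i) {
    roc_auc(.cv_scores(X, labels, folds, grid$cost[i], grid$gamma[i],
                       weight_mode = weight_mode), labels)$auc
  }, numeric(1))
  # ties: smaller cost then smaller gamma — order rows accordingly
  ord <- order(-grid$auc, grid$cost, grid$gamma)
  best <- grid[ord[1], ]
  list(cost = best$cost, gamma = best$gamma, auc = best$auc, grid = grid)
}

#' Forward wrapper selection over mRMR-ranked GO features
#'
#' Step 0 evaluates the sequence-only baseline by pooled 10-fold CV AUC;
#' step t adds the t-th ranked GO feature. Hyperparameters are tuned by
#' grid search at step 0 and held fixed afterwards unless
#' `retune_every > 0`, in which case the grid search is repeated at every
#' that-many steps.
#'
#' @param seq_features Matrix of baseline (sequence) features.
#' @param ranked_go_features Matrix of GO features already in mRMR rank
#'   order (column 1 = top-ranked).
#' @param labels 0/1 vector.
#' @param folds Fold assignment, or `NULL` to build from `seed`.
#' @param seed Seed for folds when `folds` is `NULL`.
#' @param n_folds Folds (default 10).
#' @param cost_grid,gamma_grid Grids for the baseline tuning.
#' @param retune_every 0 = tune once at baseline (default).
#' @param weight_mode Class weighting mode.
#' @return A `SelectionTrace`: list with `auc_at_step` (length k+1;
#'   entry 1 = baseline), `optimal_t`, `optimal_auc`, `cost`, `gamma`.
#' @export
forward_select <- function(seq_features, ranked_go_features, labels,
                           folds = NULL, seed = 1L, n_folds = 10L,
                           cost_grid = 2^seq(-5, 15, by = 2),
                           gamma_grid = 2^seq(-15, 3, by = 2),
                           retune_every = 0L, weight_mode = "positive") {
  Xs <- as.matrix(seq_features)
  Xg <- as.matrix(ranked_go_features)
  k <- ncol(Xg)
  if (is.null(folds)) folds <- stratified_folds(labels, n_folds, seed)
  tuned <- grid_search(Xs, labels, cost_grid, gamma_grid, folds = folds,
                       weight_mode = weight_mode)
  cost <- tuned$cost; gamma <- tuned$gamma
  auc <- numeric(k + 1L)
  auc[1] <- tuned$auc
  for (t in seq_len(k)) {
    if (retune_every > 0L && t %% retune_every == 0L) {
      tuned <- grid_search(cbind(Xs, Xg[, seq_len(t), drop = FALSE]), labels,
                           cost_grid, gamma_grid, folds = folds,
                           weight_mode = weight_mode)
      cost <- tuned$cost; gamma <- tuned$gamma
    }
    X <- cbind(Xs, Xg[, seq_len(t), drop = FALSE])
    auc[t + 1L] <- roc_auc(
      .cv_scores(X, labels, folds, cost, gamma, weight_mode = weight_mode),
      labels)$auc
  }
  optimal_t <- which.max(auc) - 1L
  structure(list(auc_at_step = auc, optimal_t = optimal_t,
                 optimal_auc = max(auc), cost = cost, gamma = gamma),
            class = "SelectionTrace")
}

#' @export
print.SelectionTrace <- function(x, ...) {
  cat(sprintf(
    "SelectionTrace: baseline AUC %.3f; optimal AUC %.3f at %d GO features\n",
    x$auc_at_step[1], x$optimal_auc, x$optimal_t))
  invisible(x)
}

#' Cross-validated stringency report
#'
#' Scores every instance exactly once via out-of-fold prediction, pools
#' the scores, and reports AUC plus Sn/Sp/Acc/Pre/MCC at the high,
#' medium, and low stringency levels (specificity > 0.95, 0.90, 0.85).
#'
#' @param features Feature matrix (already restricted to the selected
#'   feature subset).
#' @param labels 0/1 vector.
#' @param cost,gamma SVM hyperparameters.
#' @param folds Fold assignment, or `NULL` to build from `seed`.
#' @param n_folds Folds (default 10).
#' @param seed Seed for folds when `folds` is `NULL`.
#' @param sp_levels Named specificity floors.
#' @param weight_mode Class weighting mode.
#' @return A `StringencyReport`: list with `auc`, `roc`, `scores`,
#'   `levels` (data frame level, threshold, Sp, Sn, Acc, Pre, MCC).
#' @export
evaluate_cv <- function(features, labels, cost = 1, gamma = NULL,
                        folds = NULL, n_folds = 10L, seed = 1L,
                        sp_levels = c(high = 0.95, medium = 0.90, low = 0.85),
                        weight_mode = "positive") {
  X <- as.matrix(features)
  if (is.null(gamma)) gamma <- 1 / ncol(X)
  if (is.null(folds)) folds <- stratified_folds(labels, n_folds, seed)
  scores <- .cv_scores(X, labels, folds, cost, gamma,
                       weight_mode = weight_mode)
  ra <- roc_auc(scores, labels)
  rows <- lapply(names(sp_levels), function(lv) {
    m <- metrics_at_stringency(scores, labels, sp_levels[[lv]])
    data.frame(level = lv, threshold = m$threshold, Sp = m$Sp, Sn = m$Sn,
               Acc = m$Acc, Pre = m$Pre, MCC = m$MCC)
  })
  structure(list(auc = ra$auc, roc = ra$roc, scores = scores,
                 levels = do.call(rbind, rows)),
            class = "StringencyReport")
}

#' @export
print.StringencyReport <- function(x, ...) {
  cat(sprintf("StringencyReport: pooled CV AUC %.3f\n", x$auc))
  print(x$levels, row.names = FALSE, digits = 3)
  invisible(x)
}
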