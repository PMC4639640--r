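#' Empirical mutual information of two discrete vectors
#'
#' Plug-in estimate I = sum p(x,y) * ln( p(x,y) / (p(x) p(y)) ) over
#' observed cells, with 0 * ln 0 = 0. Natural-log units (nats); any
#' monotone change of base would leave mRMR rankings unchanged.
#'
#' @param x,y Equal-length discrete vectors.
#' @return Non-negative mutual information in nats.
#' @export
empirical_mutual_information <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch: x and y")
  if (!length(x)) stop("empty vectors")
  tab <- table(x, y)
  n <- sum(tab)
  pxy <- tab / n
  px <- rowSums(pxy); py <- colSums(pxy)
  terms <- pxy * log(pxy / outer(px, py))
  sum(terms[is.finite(terms) & pxy > 0])
}

# MI between one binary vector and every column of a binary matrix,
# via 2x2 cell counts from a single matrix product.
.mi_binary_vec_mat <- function(v, M) {
  n <- length(v)
  n11 <- as.numeric(crossprod(M, v))        # x=1, v=1
  c1 <- colSums(M)                          # x=1
  v1 <- sum(v)                              # v=1
  n10 <- c1 - n11
  n01 <- v1 - n11
  n00 <- n - n11 - n10 - n01
  cell <- function(nxy, nx, ny) {
    out <- numeric(length(nxy))
    pos <- nxy > 0
    out[pos] <- (nxy[pos] / n) * log(n * nxy[pos] / (nx[pos] * ny[pos]))
    out
  }
  cell(n11, c1, rep(v1, length(c1))) +
    cell(n10, c1, rep(n - v1, length(c1))) +
    cell(n01, n - c1, rep(v1, length(c1))) +
    cell(n00, n - c1, rep(n - v1, length(c1)))
}

#' mRMR ranking of binary features
#'
#' Greedy incremental minimal-redundancy maximal-relevance selection:
#' step 1 picks the feature maximizing I(x; c); each later step picks the
#' unselected feature maximizing Phi = I(x; c) - mean over selected x_j of
#' I(x; x_j). Ties break toward the lower column index. Mutual
#' information is the binary plug-in estimate in nats.
#'
#' @param features 0/1 matrix (rows = samples, columns = features).
#' @param labels 0/1 vector with both classes present.
#' @param k Number of features to rank (default 500); capped at the
#'   number of available features.
#' @return An `MRMRRanking`: list with `order` (column indices),
#'   `feature_names`, `phi_scores` (criterion value at selection time)
#'   and `relevance` (I(x; c) for every feature).
#' @export
mrmr_rank <- function(features, labels, k = 500L) {
  features <- as.matrix(features)
  storage.mode(features) <- "numeric"
  if (length(unique(labels)) < 2L)
    stop("labels contain a single class; mRMR relevance undefined")
  if (!ncol(features)) stop("no features supplied")
  Fn <- ncol(features)
  k <- min(as.integer(k), Fn)
  rel <- .mi_binary_vec_mat(as.numeric(labels), features)

  order_ <- integer(k)
  phi <- numeric(k)
  selected <- logical(Fn)
  redsum <- numeric(Fn)
  for (t in seq_len(k)) {
    score <- if (t == 1L) rel else rel - redsum / (t - 1L)
    score[selected] <- -Inf
    j <- which.max(score)          # which.max takes the first (lowest index) tie
    order_[t] <- j
    phi[t] <- score[j]
    selected[j] <- TRUE
    if (t < k)
      redsum <- redsum + .mi_binary_vec_mat(features[, j], features)
  }
  structure(list(order = order_,
                 feature_names = colnames(features)[order_],
                 phi_scores = phi,
                 relevance = rel),
            class = "MRMRRanking")
}

#' @export
print.MRMRRanking <- function(x, ...) {
  cat("MRMRRanking:", length(x$order), "features; top:",
      paste(head(x$feature_names %||% x$order, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Write an mRMR ranking as TSV (rank, feature, phi)
#' @param ranking An `MRMRRanking`.
#' @param path Output file.
#' @export
write_ranking <- function(ranking, path) {
  df <- data.frame(rank = seq_along(ranking$order),
                   feature = ranking$feature_names %||% ranking$order,
                   column = ranking$order,
                   phi = ranking$phi_scores)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
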