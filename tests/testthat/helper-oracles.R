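# Independent brute-force oracles. These deliberately avoid the code paths
# of the functions they check.

# mutual information by explicit loops over observed value pairs
mi_oracle <- function(x, y) {
  n <- length(x)
  total <- 0
  for (a in unique(x)) for (b in unique(y)) {
    nab <- sum(x == a & y == b)
    if (nab == 0) next
    pa <- sum(x == a) / n
    pb <- sum(y == b) / n
    total <- total + (nab / n) * log((nab / n) / (pa * pb))
  }
  total
}

# AUC by counting concordant / tied positive-negative pairs
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

# KS D by evaluating both ECDFs at every sample point of either sample
ks_oracle <- function(a, b) {
  best <- 0
  for (t in c(a, b)) {
    d <- abs(sum(a <= t) / length(a) - sum(b <= t) / length(b))
    if (d > best) best <- d
  }
  best
}

# two-tailed Fisher p by enumerating every table with the observed margins,
# probabilities from binomial coefficients
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; N <- a + b + c + d
  prob_of <- function(k) {
    choose(r1, k) * choose(r2, c1 - k) / choose(N, c1)
  }
  p_obs <- prob_of(a)
  total <- 0
  for (k in max(0, c1 - r2):min(r1, c1)) {
    pk <- prob_of(k)
    if (pk <= p_obs * (1 + 1e-7)) total <- total + pk
  }
  min(1, total)
}

# naive mRMR: re-evaluates the full criterion for every candidate at every
# step using the scalar MI function
mrmr_oracle <- function(X, labels, k) {
  Fn <- ncol(X)
  k <- min(k, Fn)
  rel <- vapply(seq_len(Fn), function(j)
    empirical_mutual_information(X[, j], labels), numeric(1))
  sel <- integer(0)
  phi <- numeric(0)
  for (t in seq_len(k)) {
    cand <- setdiff(seq_len(Fn), sel)
    score <- vapply(cand, function(j) {
      red <- if (length(sel))
        mean(vapply(sel, function(s)
          empirical_mutual_information(X[, j], X[, s]), numeric(1)))
      else 0
      rel[j] - red
    }, numeric(1))
    best <- cand[which.max(score)]   # first max = lowest index
    sel <- c(sel, best)
    phi <- c(phi, max(score))
  }
  list(order = sel, phi = phi)
}
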