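#' Two-tailed Fisher GO enrichment with Bonferroni correction
#'
#' Every GO term annotating at least one foreground protein is tested on
#' the 2x2 table (foreground with/without the term vs background
#' with/without). The two-tailed p is the sum of hypergeometric
#' probabilities of all tables with the same margins that are as probable
#' as or less probable than the observed one. A term passes when its
#' fold-enrichment ratio exceeds `ratio_min` and its Bonferroni-adjusted
#' p is below `alpha`.
#'
#' @param fg_proteins,bg_proteins Character vectors of protein ids
#'   (unannotated proteins still count in the totals).
#' @param go A `GOAnnotationMap`.
#' @param ratio_min Fold-enrichment floor (default 4).
#' @param alpha Significance level on the Bonferroni p (default 0.05).
#' @return Data frame (one row per tested term, sorted by p_bonferroni):
#'   term, fg_count, fg_total, bg_count, bg_total, ratio, p_raw,
#'   p_bonferroni, passes.
#' @export
fisher_enrichment <- function(fg_proteins, bg_proteins, go,
                              ratio_min = 4, alpha = 0.05) {
  fg <- unique(fg_proteins); bg <- unique(bg_proteins)
  if (!length(fg) || !length(bg)) stop("foreground and background must be non-empty")
  fg_terms <- sort(unique(unlist(lapply(fg, go_terms_of, go = go))))
  if (!length(fg_terms))
    return(data.frame(term = character(0), fg_count = integer(0),
                      fg_total = integer(0), bg_count = integer(0),
                      bg_total = integer(0), ratio = numeric(0),
                      p_raw = numeric(0), p_bonferroni = numeric(0),
                      passes = logical(0)))
  n_fg <- length(fg); n_bg <- length(bg)
  rows <- lapply(fg_terms, function(term) {
    a <- sum(vapply(fg, function(p) term %in% go_terms_of(go, p), logical(1)))
    c_ <- sum(vapply(bg, function(p) term %in% go_terms_of(go, p), logical(1)))
    p <- fisher_two_tailed(a, n_fg - a, c_, n_bg - c_)
    ratio <- if (c_ > 0) (a / n_fg) / (c_ / n_bg) else Inf
    data.frame(term = term, fg_count = a, fg_total = n_fg,
               bg_count = c_, bg_total = n_bg, ratio = ratio, p_raw = p)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p_raw * nrow(out))
  out$passes <- out$ratio > ratio_min & out$p_bonferroni < alpha
  out <- out[order(out$p_bonferroni, out$p_raw, out$term), ]
  rownames(out) <- NULL
  out
}

#' Two-tailed Fisher exact p for a 2x2 table
#'
#' Sums hypergeometric probabilities of every table with the observed
#' margins whose probability does not exceed the observed table's
#' (within a 1 + 1e-7 relative guard against floating-point ties).
#'
#' @param a,b,c,d Cell counts: a = fg with term, b = fg without,
#'   c = bg with, d = bg without.
#' @return p-value in \[0, 1\].
#' @export
fisher_two_tailed <- function(a, b, c, d) {
  m <- a + c       # total with term
  n <- b + d       # total without
  k <- a + b       # foreground size
  support <- max(0L, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}
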