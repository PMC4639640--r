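#' Build a ratio-controlled labeled training set
#'
#' All cross-talk sites enter as positives. Negatives are drawn uniformly
#' without replacement from the single-modification class matching the
#' basis: `phos_based` uses phospho-only sites (default negative:positive
#' ratio 10), `glcnac_based` uses O-GlcNAc-only sites (default ratio 2).
#' If fewer negatives exist than `round(ratio * positives)`, all are used
#' and a warning records the achieved ratio.
#'
#' @param catalog A `SiteCatalog`.
#' @param basis `"phos_based"` or `"glcnac_based"`.
#' @param neg_pos_ratio Positive number; default 10 for `phos_based`,
#'   2 for `glcnac_based`.
#' @param seed Integer seed for negative sampling.
#' @return A `TrainingSet`: list with `instances` (data frame protein_id,
#'   position, residue), `labels` (integer 0/1), `basis`, `neg_pos_ratio`
#'   (requested) and `achieved_ratio`.
#' @export
build_training_set <- function(catalog,
                               basis = c("phos_based", "glcnac_based"),
                               neg_pos_ratio = NULL, seed = 1L) {
  basis <- match.arg(basis)
  if (is.null(neg_pos_ratio))
    neg_pos_ratio <- if (basis == "phos_based") 10 else 2
  stopifnot(neg_pos_ratio > 0)
  cls <- catalog$classes
  pos <- cls[cls$class == "crosstalk", , drop = FALSE]
  if (nrow(pos) == 0L) stop("catalog contains no crosstalk (positive) sites")
  neg_class <- if (basis == "phos_based") "phospho_only" else "oglcnac_only"
  negpool <- cls[cls$class == neg_class, , drop = FALSE]
  n_wanted <- round(neg_pos_ratio * nrow(pos))
  if (nrow(negpool) < n_wanted) {
    warning(sprintf(
      "only %d %s negatives available (wanted %d); achieved ratio %.3f",
      nrow(negpool), neg_class, n_wanted, nrow(negpool) / nrow(pos)))
    neg <- negpool
  } else {
    idx <- with_seed(seed, sample.int(nrow(negpool), n_wanted))
    neg <- negpool[sort(idx), , drop = FALSE]
  }
  instances <- rbind(pos[c("protein_id", "position", "residue")],
                     neg[c("protein_id", "position", "residue")])
  rownames(instances) <- NULL
  structure(list(instances = instances,
                 labels = c(rep(1L, nrow(pos)), rep(0L, nrow(neg))),
                 basis = basis,
                 neg_pos_ratio = neg_pos_ratio,
                 achieved_ratio = nrow(neg) / nrow(pos)),
            class = "TrainingSet")
}

#' @export
print.TrainingSet <- function(x, ...) {
  cat(sprintf("TrainingSet (%s): %d positives, %d negatives (ratio %.2f)\n",
              x$basis, sum(x$labels == 1L), sum(x$labels == 0L),
              x$achieved_ratio))
  invisible(x)
}
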