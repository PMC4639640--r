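#' Extract a 21-residue window around a modified site
#'
#' Positions falling outside the sequence (sites near a terminus) are
#' padded with `*`.
#'
#' @param sequence Protein sequence (character scalar).
#' @param position 1-based site position.
#' @param flank Residues on each side (default 10, giving width 21).
#' @return Character scalar of width `2 * flank + 1`. A warning is raised
#'   (window still produced) if the central residue is not S or T.
#' @export
extract_window <- function(sequence, position, flank = 10L) {
  n <- nchar(sequence)
  stopifnot(position >= 1L, position <= n)
  idx <- (position - flank):(position + flank)
  chars <- rep("*", length(idx))
  inside <- idx >= 1L & idx <= n
  chars[inside] <- substring(sequence, idx[inside], idx[inside])
  center <- chars[flank + 1L]
  if (!center %in% c("S", "T"))
    warning("window center residue is '", center, "', not S/T")
  paste(chars, collapse = "")
}

#' Feature names for the sparse sequence encoding
#' @param flank Window half-width (default 10).
#' @return Character vector of `(2*flank+1) * 21` names, `pos{offset}:{letter}`.
#' @export
seq_feature_names <- function(flank = 10L) {
  offs <- (-flank):flank
  as.vector(t(outer(offs, AA_ALPHABET21,
                    function(o, a) sprintf("pos%+d:%s", o, a))))
}

#' Sparse one-hot encoding of a sequence window
#'
#' Each of the 21 window positions is coded as a 21-bit one-hot block over
#' the alphabet A..Y then `*` (alphabetical amino acids, padding symbol
#' last); blocks are concatenated in window order, giving 441 bits with
#' exactly 21 ones. Characters outside the alphabet map to `*` with a
#' warning.
#'
#' @param window Character scalar (width `2*flank+1`).
#' @param flank Window half-width (default 10).
#' @return Integer 0/1 vector of length `(2*flank+1) * 21`.
#' @export
encode_window <- function(window, flank = 10L) {
  w <- 2L * flank + 1L
  stopifnot(nchar(window) == w)
  chars <- strsplit(window, "", fixed = TRUE)[[1]]
  slot <- match(chars, AA_ALPHABET21)
  if (anyNA(slot)) {
    warning("non-standard letter(s) mapped to '*': ",
            paste(unique(chars[is.na(slot)]), collapse = ", "))
    slot[is.na(slot)] <- 21L
  }
  v <- integer(w * 21L)
  v[(seq_len(w) - 1L) * 21L + slot] <- 1L
  v
}

#' Assemble the binary feature matrix for a training set
#'
#' Rows follow the training-set instance order. The first
#' `(2*flank+1)*21` columns are the sparse sequence encoding; the
#' remaining columns are per-protein GO indicators in universe order
#' (proteins without annotation get an all-zero GO block).
#'
#' @param training A `TrainingSet` (or data frame with `protein_id`,
#'   `position`).
#' @param proteins Named character vector of sequences.
#' @param go A `GOAnnotationMap`, or `NULL` for sequence features only.
#' @param flank Window half-width (default 10).
#' @return A `FeatureMatrix`: integer matrix with attributes
#'   `n_seq_cols` and `instances`; `colnames` are sequence feature names
#'   followed by GO term ids.
#' @export
assemble_features <- function(training, proteins, go = NULL, flank = 10L) {
  inst <- if (inherits(training, "TrainingSet")) training$instances else training
  missing_p <- setdiff(unique(inst$protein_id), names(proteins))
  if (length(missing_p))
    stop("no sequence for protein(s): ", paste(missing_p, collapse = ", "))
  seq_block <- t(vapply(seq_len(nrow(inst)), function(i) {
    encode_window(extract_window(proteins[[inst$protein_id[i]]],
                                 inst$position[i], flank), flank)
  }, integer((2L * flank + 1L) * 21L)))
  colnames(seq_block) <- seq_feature_names(flank)
  universe <- if (is.null(go)) character(0) else go$universe
  if (length(universe)) {
    prot_ids <- unique(inst$protein_id)
    blocks <- matrix(vapply(prot_ids, function(p) {
      as.integer(universe %in% go_terms_of(go, p))
    }, integer(length(universe))), nrow = length(universe))
    go_block <- t(blocks)[match(inst$protein_id, prot_ids), , drop = FALSE]
    colnames(go_block) <- universe
    mat <- cbind(seq_block, go_block)
  } else {
    mat <- seq_block
  }
  rownames(mat) <- NULL
  structure(mat, n_seq_cols = ncol(seq_block), instances = inst,
            class = c("FeatureMatrix", class(mat)))
}

#' Write a feature matrix (with optional labels) as TSV
#' @param x A `FeatureMatrix`.
#' @param path Output file.
#' @param labels Optional 0/1 label vector appended as a `label` column.
#' @export
write_feature_matrix <- function(x, path, labels = NULL) {
  inst <- attr(x, "instances")
  df <- cbind(inst[c("protein_id", "position")], as.data.frame(unclass(x)))
  if (!is.null(labels)) df$label <- labels
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
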