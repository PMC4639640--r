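#' Construct an ortholog alignment object
#'
#' @param rows Named character vector of aligned sequences (equal length,
#'   gaps as `-`).
#' @param reference_id Name of the reference-species row.
#' @return An `OrthologAlignment`.
#' @export
ortholog_alignment <- function(rows, reference_id) {
  stopifnot(length(rows) >= 2L)
  w <- unique(nchar(rows))
  if (length(w) != 1L) stop("alignment rows have unequal lengths")
  if (!reference_id %in% names(rows))
    stop("reference id '", reference_id, "' not present in alignment")
  structure(list(rows = toupper(rows), reference_id = reference_id,
                 n_total = length(rows), width = w),
            class = "OrthologAlignment")
}

#' Read an aligned FASTA file as an OrthologAlignment
#' @param path Aligned FASTA file.
#' @param reference_id Id of the reference row.
#' @return An `OrthologAlignment`.
#' @export
read_alignment <- function(path, reference_id) {
  ortholog_alignment(read_fasta(path), reference_id)
}

#' Map an ungapped reference position to an alignment column
#'
#' @param aln An `OrthologAlignment`.
#' @param ref_pos 1-based position in the ungapped reference sequence.
#' @return 1-based alignment column index.
#' @export
map_reference_position <- function(aln, ref_pos) {
  ref <- strsplit(aln$rows[[aln$reference_id]], "", fixed = TRUE)[[1]]
  non_gap <- which(ref != "-")
  if (ref_pos < 1L || ref_pos > length(non_gap))
    stop("reference position ", ref_pos, " out of range (ungapped length ",
         length(non_gap), ")")
  non_gap[ref_pos]
}

#' Residue conservation ratio (RCR) at a reference position
#'
#' RCR = N_c / N_total, where N_c counts alignment rows (reference
#' included) whose character at the mapped column equals the reference
#' residue exactly, and N_total is the number of rows. Gap characters
#' count in N_total but never in N_c; S and T are not interchangeable.
#'
#' @inheritParams map_reference_position
#' @return Fraction in \[0, 1\].
#' @export
compute_rcr <- function(aln, ref_pos) {
  col <- map_reference_position(aln, ref_pos)
  chars <- substring(aln$rows, col, col)
  ref_char <- substring(aln$rows[[aln$reference_id]], col, col)
  sum(chars == ref_char) / aln$n_total
}

#' Relative RCR: percentile of a site's RCR within its flanking region
#'
#' The reference distribution is the RCR of every reference residue in
#' the +/-20 window around the site, excluding the site itself and
#' truncated at the protein termini. The percentile uses mid-ranking for
#' ties: (#flanking < site + 0.5 * #flanking == site) / #flanking, so a
#' uniformly conserved region scores 0.5.
#'
#' @inheritParams map_reference_position
#' @param flank Window half-width in residues (default 20).
#' @return List with `rcr`, `rrcr`, `flanking_rcrs` (site excluded) and
#'   `window_rcrs` (site included).
#' @export
compute_rrcr <- function(aln, ref_pos, flank = 20L) {
  ref <- gsub("-", "", aln$rows[[aln$reference_id]], fixed = TRUE)
  n <- nchar(ref)
  if (n < 2L) stop("reference protein shorter than 2 residues")
  lo <- max(1L, ref_pos - flank); hi <- min(n, ref_pos + flank)
  rcrs <- .rcr_range(aln, lo:hi)
  site_rcr <- rcrs[ref_pos - lo + 1L]
  flanking <- rcrs[-(ref_pos - lo + 1L)]
  rrcr <- (sum(flanking < site_rcr) + 0.5 * sum(flanking == site_rcr)) /
    length(flanking)
  # window_rcrs includes the site (2*flank+1 entries for interior sites);
  # the percentile reference distribution (flanking_rcrs) excludes it
  list(rcr = site_rcr, rrcr = rrcr, flanking_rcrs = flanking,
       window_rcrs = rcrs)
}

# Vectorized RCR over several ungapped reference positions: one pass over
# the character matrix instead of one strsplit per position.
.rcr_range <- function(aln, ref_positions) {
  mat <- do.call(rbind, strsplit(unname(aln$rows), "", fixed = TRUE))
  ref_row <- mat[match(aln$reference_id, names(aln$rows)), ]
  non_gap <- which(ref_row != "-")
  cols <- non_gap[ref_positions]
  vapply(seq_along(cols), function(k) {
    sum(mat[, cols[k]] == ref_row[cols[k]]) / aln$n_total
  }, numeric(1))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum absolute difference of the two empirical CDFs; the
#' p-value uses the asymptotic Kolmogorov distribution at effective sample
#' size n_a * n_b / (n_a + n_b).
#'
#' @param a,b Non-empty numeric samples.
#' @return List with `D` and `p_value`.
#' @export
ks_two_sample <- function(a, b) {
  if (!length(a) || !length(b)) stop("KS test requires non-empty samples")
  pts <- sort(unique(c(a, b)))
  Fa <- vapply(pts, function(t) mean(a <= t), numeric(1))
  Fb <- vapply(pts, function(t) mean(b <= t), numeric(1))
  D <- max(abs(Fa - Fb))
  ne <- length(a) * length(b) / (length(a) + length(b))
  lambda <- sqrt(ne) * D
  # asymptotic Kolmogorov survival function
  if (lambda < 1e-10) p <- 1 else {
    j <- 1:100
    p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))
    p <- min(1, max(0, p))
  }
  list(D = D, p_value = p)
}

#' Mean conservation over a motif's fixed positions
#'
#' Arithmetic mean of [compute_rcr()] over the motif occurrence's fixed
#' (non-wildcard) positions, the central modified residue included.
#'
#' @param aln An `OrthologAlignment`.
#' @param positions 1-based ungapped reference positions of the fixed
#'   motif residues.
#' @return Fraction in \[0, 1\].
#' @export
motif_conservation <- function(aln, positions) {
  if (!length(positions)) stop("motif has no fixed positions")
  mean(vapply(positions, function(p) compute_rcr(aln, p), numeric(1)))
}

#' Per-site conservation profiles for a catalog
#'
#' @param catalog A `SiteCatalog`.
#' @param alignments Named list of `OrthologAlignment`, keyed by protein id.
#' @param flank Window half-width for the rRCR reference (default 20).
#' @return Data frame with protein_id, position, class, rcr, rrcr; sites
#'   with no alignment are skipped with a warning.
#' @export
conservation_profiles <- function(catalog, alignments, flank = 20L) {
  cls <- catalog$classes
  have <- cls$protein_id %in% names(alignments)
  if (any(!have))
    warning(sum(!have), " site(s) skipped: no alignment for their protein")
  cls <- cls[have, , drop = FALSE]
  prof <- lapply(seq_len(nrow(cls)), function(i) {
    r <- compute_rrcr(alignments[[cls$protein_id[i]]], cls$position[i], flank)
    data.frame(protein_id = cls$protein_id[i], position = cls$position[i],
               class = cls$class[i], rcr = r$rcr, rrcr = r$rrcr,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, prof)
  rownames(out) <- NULL
  out
}
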