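#' Render a motif pattern string
#'
#' Fixed offsets map to residue letters; the central modified residue is
#' bracketed; unfixed positions render as `x`, with leading/trailing
#' wildcards trimmed. E.g. P fixed at offset -3 around S gives
#' `"Pxx[S]"`.
#'
#' @param center `"S"` or `"T"`.
#' @param fixed Named numeric-offset map, e.g. `c("-3" = "P")`; offsets
#'   are relative to the center (offset 0 is the center itself and is
#'   implied).
#' @param flank Window half-width (default 10).
#' @return Character scalar.
#' @export
motif_to_string <- function(center, fixed = c(), flank = 10L) {
  offs <- (-flank):flank
  chars <- rep("x", length(offs))
  chars[offs == 0L] <- paste0("[", center, "]")
  if (length(fixed)) {
    io <- as.integer(names(fixed))
    stopifnot(all(io != 0L), all(abs(io) <= flank))
    chars[match(io, offs)] <- unname(fixed)
  }
  first <- min(which(chars != "x")); last <- max(which(chars != "x"))
  paste(chars[first:last], collapse = "")
}

#' Parse a motif pattern string
#' @param s Pattern such as `"Pxx[S]"` or `"[T]xxxxxxxxxP"`.
#' @param flank Window half-width (default 10).
#' @return List with `center` and `fixed` (named character vector keyed
#'   by offset), inverse of [motif_to_string()].
#' @export
parse_motif <- function(s, flank = 10L) {
  m <- regexpr("\\[[ST]\\]", s)
  if (m < 0) stop("motif string lacks a bracketed [S]/[T] center: ", s)
  center <- substring(s, m + 1, m + 1)
  left <- substring(s, 1, m - 1)
  right <- substring(s, m + 3)
  lchars <- if (nchar(left)) strsplit(left, "", fixed = TRUE)[[1]] else character(0)
  rchars <- if (nchar(right)) strsplit(right, "", fixed = TRUE)[[1]] else character(0)
  offs <- c(rev(seq_along(lchars)) * -1, seq_along(rchars))
  chars <- c(lchars, rchars)
  keep <- chars != "x"
  fixed <- setNames(chars[keep], offs[keep])
  list(center = center, fixed = fixed)
}

#' Which windows match a motif
#' @param windows Character vector of 21-residue windows.
#' @param motif A motif as returned by [parse_motif()] /
#'   [motifx_extract()] (list with `center`, `fixed`).
#' @param flank Window half-width (default 10).
#' @return Logical vector.
#' @export
motif_matches <- function(windows, motif, flank = 10L) {
  ok <- substring(windows, flank + 1L, flank + 1L) == motif$center
  for (o in names(motif$fixed)) {
    i <- as.integer(o) + flank + 1L
    ok <- ok & substring(windows, i, i) == motif$fixed[[o]]
  }
  ok
}

#' motif-x style overrepresented motif extraction
#'
#' Iterative position/residue fixation: at each step, for every
#' (offset != 0, residue) pair the binomial tail P(X >= k_fg) is computed
#' with X ~ Binomial(n_fg, f_bg), where k_fg is the foreground count of
#' that residue at that offset and f_bg its frequency in the current
#' background. The most significant pair is fixed if its p is below
#' `p_threshold` and k_fg >= `min_count`; both window sets are then
#' restricted to matching windows and the scan repeats. When no pair
#' qualifies, the accumulated motif (if any position was fixed) is
#' emitted, its foreground and background matches are removed, and the
#' procedure restarts on the remainder.
#'
#' @param fg_windows,bg_windows Character vectors of width-`2*flank+1`
#'   windows centered on the same residue class.
#' @param p_threshold Binomial significance threshold (default 1e-6).
#' @param min_count Minimum foreground occurrences (default 20).
#' @param flank Window half-width (default 10).
#' @return List of motifs; each has `center`, `fixed`, `pattern` (string
#'   form), `fg_matches`, `bg_matches`, and `step_pvalues`.
#' @export
motifx_extract <- function(fg_windows, bg_windows, p_threshold = 1e-6,
                           min_count = 20L, flank = 10L) {
  w <- 2L * flank + 1L
  stopifnot(all(nchar(fg_windows) == w), all(nchar(bg_windows) == w))
  centers <- unique(substring(c(fg_windows, bg_windows), flank + 1L, flank + 1L))
  if (length(centers) > 1L)
    stop("mixed center residues (", paste(centers, collapse = ", "),
         "); run motifx_extract per center class")
  fg_pool <- fg_windows
  bg_pool <- bg_windows
  motifs <- list()
  repeat {
    if (length(fg_pool) < min_count) break
    fg <- fg_pool; bg <- bg_pool
    fixed <- character(0)
    pvals <- numeric(0)
    repeat {
      best <- .motifx_best_pair(fg, bg, flank, setdiff(seq_len(w), flank + 1L),
                                fixed)
      if (is.null(best) || best$p >= p_threshold || best$k < min_count) break
      fixed[as.character(best$offset)] <- best$residue
      pvals <- c(pvals, best$p)
      sel_fg <- substring(fg, best$col, best$col) == best$residue
      sel_bg <- substring(bg, best$col, best$col) == best$residue
      fg <- fg[sel_fg]; bg <- bg[sel_bg]
      if (!length(bg)) break
    }
    if (!length(fixed)) break
    center <- substring(fg[1], flank + 1L, flank + 1L)
    motif <- list(center = center, fixed = fixed,
                  pattern = motif_to_string(center, fixed, flank),
                  fg_matches = length(fg), bg_matches = length(bg),
                  step_pvalues = pvals)
    motifs[[length(motifs) + 1L]] <- motif
    keep_fg <- !motif_matches(fg_pool, motif, flank)
    keep_bg <- !motif_matches(bg_pool, motif, flank)
    fg_pool <- fg_pool[keep_fg]
    bg_pool <- bg_pool[keep_bg]
  }
  motifs
}

# Most significant (offset, residue) fixation candidate.
.motifx_best_pair <- function(fg, bg, flank, cols, fixed) {
  n_fg <- length(fg); n_bg <- length(bg)
  cols <- cols[!(cols - flank - 1L) %in% as.integer(names(fixed))]
  best <- NULL
  for (col in cols) {
    fg_chars <- substring(fg, col, col)
    bg_chars <- substring(bg, col, col)
    for (res in AA20) {
      k <- sum(fg_chars == res)
      if (k == 0L) next
      f_bg <- sum(bg_chars == res) / n_bg
      p <- if (f_bg >= 1) 1 else pbinom(k - 1L, n_fg, f_bg, lower.tail = FALSE)
      if (is.null(best) || p < best$p) {
        best <- list(offset = col - flank - 1L, residue = res, col = col,
                     k = k, p = p)
      }
    }
  }
  best
}

#' End-to-end motif pipeline with conservation filter and enrichment
#'
#' Extracts overrepresented motifs from cross-talk-site windows against
#' all S/T-centered windows of the proteome, scores every motif
#' occurrence's conservation on the ortholog alignments (mean RCR over
#' fixed positions), drops occurrences below `conservation_min`, and runs
#' GO enrichment of the surviving proteins against the proteins that
#' carry cross-talk sites. A motif is flagged `functional` when at least
#' one term is enriched at raw p below `alpha`.
#'
#' @param catalog A `SiteCatalog`.
#' @param proteins Named character vector of sequences (the proteome).
#' @param alignments Named list of `OrthologAlignment` keyed by protein
#'   id (occurrences on proteins without an alignment are skipped with a
#'   warning).
#' @param go A `GOAnnotationMap`.
#' @param p_threshold,min_count motif-x parameters.
#' @param conservation_min Conservation filter (default 0.4; occurrences
#'   scoring exactly 0.4 are retained).
#' @param alpha Enrichment significance level on raw p (default 0.05).
#' @param flank Window half-width (default 10).
#' @return List of `MotifResult`s: motif fields plus `occurrences` (data
#'   frame protein_id, position, conservation, kept), `surviving_proteins`,
#'   `enrichment`, `functional`.
#' @export
motif_pipeline <- function(catalog, proteins, alignments, go,
                           p_threshold = 1e-6, min_count = 20L,
                           conservation_min = 0.4, alpha = 0.05,
                           flank = 10L) {
  cls <- catalog$classes
  ct <- cls[cls$class == "crosstalk", , drop = FALSE]
  fg_windows <- vapply(seq_len(nrow(ct)), function(i) {
    extract_window(proteins[[ct$protein_id[i]]], ct$position[i], flank)
  }, character(1))
  bg <- all_st_windows(proteins, flank)
  # motif-x runs per central residue class
  motifs <- list()
  for (ctr in c("S", "T")) {
    fg_c <- fg_windows[substring(fg_windows, flank + 1L, flank + 1L) == ctr]
    bg_c <- bg$window[substring(bg$window, flank + 1L, flank + 1L) == ctr]
    if (length(fg_c) && length(bg_c))
      motifs <- c(motifs, motifx_extract(fg_c, bg_c, p_threshold,
                                         min_count, flank))
  }
  bg_proteins <- unique(ct$protein_id)  # proteins containing crosstalk sites
  lapply(motifs, function(motif) {
    hit <- motif_matches(bg$window, motif, flank)
    occ <- bg[hit, c("protein_id", "position")]
    fixed_offsets <- c(0L, as.integer(names(motif$fixed)))
    cons <- rep(NA_real_, nrow(occ))
    for (i in seq_len(nrow(occ))) {
      aln <- alignments[[occ$protein_id[i]]]
      if (is.null(aln)) next
      pos <- occ$position[i] + fixed_offsets
      n <- nchar(gsub("-", "", aln$rows[[aln$reference_id]], fixed = TRUE))
      pos <- pos[pos >= 1L & pos <= n]
      cons[i] <- motif_conservation(aln, pos)
    }
    if (anyNA(cons))
      warning(sum(is.na(cons)), " occurrence(s) of ", motif$pattern,
              " skipped: no alignment")
    occ$conservation <- cons
    occ$kept <- !is.na(cons) & cons >= conservation_min
    surviving <- unique(occ$protein_id[occ$kept])
    enr <- if (length(surviving))
      fisher_enrichment(surviving, bg_proteins, go, alpha = alpha)
    else NULL
    functional <- !is.null(enr) && any(enr$p_raw < alpha)
    c(motif, list(occurrences = occ, surviving_proteins = surviving,
                  enrichment = enr, functional = functional))
  })
}

#' All S/T-centered windows of a proteome
#' @param proteins Named character vector of sequences.
#' @param flank Window half-width (default 10).
#' @return Data frame with protein_id, position, window.
#' @export
all_st_windows <- function(proteins, flank = 10L) {
  rows <- lapply(names(proteins), function(id) {
    seq <- proteins[[id]]
    pos <- which(strsplit(seq, "", fixed = TRUE)[[1]] %in% c("S", "T"))
    if (!length(pos)) return(NULL)
    data.frame(protein_id = id, position = pos,
               window = vapply(pos, function(p)
                 extract_window(seq, p, flank), character(1)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
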