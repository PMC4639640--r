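# In-code fixtures shared across test files.

# toy catalog: each site on its own protein, S at position 6 of an
# 11-residue protein
toy_catalog <- function(n_crosstalk, n_phospho, n_oglcnac, seed = 1) {
  n <- n_crosstalk + n_phospho + n_oglcnac
  ids <- sprintf("P%03d", seq_len(n))
  seqs <- setNames(withr::with_seed(seed, vapply(seq_len(n), function(i) {
    chars <- sample(setdiff(LETTERS[LETTERS %in% strsplit(
      "ACDEFGHIKLMNPQRSTVWY", "")[[1]]], "S"), 11, replace = TRUE)
    chars[6] <- "S"
    paste(chars, collapse = "")
  }, character(1))), ids)
  cls <- rep(c("crosstalk", "phospho_only", "oglcnac_only"),
             c(n_crosstalk, n_phospho, n_oglcnac))
  mods <- list(crosstalk = c("phospho", "oglcnac"),
               phospho_only = "phospho", oglcnac_only = "oglcnac")
  rows <- do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(protein_id = ids[i], position = 6L, residue = "S",
               modification = mods[[cls[i]]], stringsAsFactors = FALSE)))
  list(proteins = seqs, catalog = site_catalog(rows, seqs))
}

# alignment with controlled per-column match counts: matches[k] rows agree
# with the reference at column k (reference row included in the count)
toy_alignment <- function(ref_chars, matches, n_rows = 10) {
  w <- length(ref_chars)
  stopifnot(length(matches) == w, all(matches >= 1), all(matches <= n_rows))
  rows <- matrix("", n_rows, w)
  rows[1, ] <- ref_chars
  for (k in seq_len(w)) {
    alt <- if (ref_chars[k] == "V") "W" else "V"   # guaranteed mismatch
    rows[, k] <- c(rep(ref_chars[k], matches[k]),
                   rep(alt, n_rows - matches[k]))
  }
  seqs <- apply(rows, 1, paste, collapse = "")
  names(seqs) <- c("ref", paste0("sp", seq_len(n_rows - 1)))
  ortholog_alignment(seqs, "ref")
}

# random width-21 windows with a fixed center
random_windows <- function(n, center = "S", seed = 1) {
  withr::with_seed(seed, vapply(seq_len(n), function(i) {
    chars <- sample(ptmx:::AA20, 21, replace = TRUE)
    chars[11] <- center
    paste(chars, collapse = "")
  }, character(1)))
}

# plant a motif (parse_motif form) into a window string
plant_motif <- function(window, motif) {
  chars <- strsplit(window, "", fixed = TRUE)[[1]]
  chars[11] <- motif$center
  for (o in names(motif$fixed))
    chars[as.integer(o) + 11] <- motif$fixed[[o]]
  paste(chars, collapse = "")
}
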