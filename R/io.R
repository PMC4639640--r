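#' Read protein sequences from a FASTA file
#'
#' Sequences are upper-cased on load. Record identifiers are the first
#' whitespace-delimited token of each header and must be unique.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of protein sequences (names = ids).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0L) return(setNames(character(0), character(0)))
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  if (any(ids == "")) stop("FASTA record ", which(ids == "")[1], " has an empty header")
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate FASTA ids: ", paste(unique(dup), collapse = ", "))
  empty <- which(nchar(seqs) == 0L)
  if (length(empty)) stop("empty sequence for record '", ids[empty[1]], "'")
  names(seqs) <- ids
  seqs
}

#' Read a PTM site table and classify sites
#'
#' Reads a TSV with header columns `protein_id`, `position`, `residue`,
#' `modification` (values `phospho` / `oglcnac`), validates each row
#' against the protein sequences, and partitions the distinct
#' (protein, position) pairs into three classes: `crosstalk` (both
#' modification types recorded at the same residue), `phospho_only`,
#' `oglcnac_only`. Duplicate identical rows collapse silently; rows whose
#' residue letter disagrees with the sequence (or whose position is out of
#' bounds) are rejected and counted.
#'
#' @param path Path to the site TSV.
#' @param proteins Named character vector of sequences (see [read_fasta()]).
#' @return A `SiteCatalog`: list with `sites` (validated rows), `classes`
#'   (one row per distinct protein+position with a `class` column), and
#'   `rejected` (rejected rows with a `reason` column).
#' @export
read_site_table <- function(path, proteins) {
  if (!file.exists(path)) stop("site table not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "position", "residue", "modification")
  if (!all(need %in% names(df)))
    stop("site table must have columns: ", paste(need, collapse = ", "))
  df <- df[need]
  df$position <- as.integer(df$position)
  df$residue <- toupper(df$residue)
  df$modification <- tolower(df$modification)
  bad_mod <- !df$modification %in% c("phospho", "oglcnac")
  if (any(bad_mod))
    stop("unknown modification value(s): ",
         paste(unique(df$modification[bad_mod]), collapse = ", "))
  site_catalog(df, proteins)
}

#' Build a SiteCatalog from an in-memory site data frame
#'
#' @param sites Data frame with columns `protein_id`, `position`,
#'   `residue`, `modification`.
#' @param proteins Named character vector of sequences.
#' @return A `SiteCatalog` (see [read_site_table()]).
#' @export
site_catalog <- function(sites, proteins) {
  df <- unique(sites)
  reason <- rep(NA_character_, nrow(df))
  known <- df$protein_id %in% names(proteins)
  reason[!known] <- "unknown protein"
  len <- rep(NA_integer_, nrow(df))
  len[known] <- nchar(proteins[df$protein_id[known]])
  inb <- known & df$position >= 1L & df$position <= len
  reason[known & !inb] <- "position out of bounds"
  obs <- rep(NA_character_, nrow(df))
  obs[inb] <- substring(proteins[df$protein_id[inb]], df$position[inb],
                        df$position[inb])
  match_res <- inb & obs == df$residue
  reason[inb & !match_res] <- "residue mismatch"
  ok <- match_res & df$residue %in% c("S", "T")
  reason[match_res & !ok] <- "residue not S/T"

  rejected <- df[!ok, , drop = FALSE]
  rejected$reason <- reason[!ok]
  kept <- df[ok, , drop = FALSE]
  if (nrow(rejected))
    message(nrow(rejected), " site row(s) rejected on load")

  key <- paste(kept$protein_id, kept$position, sep = "\r")
  has_p <- tapply(kept$modification == "phospho", key, any)
  has_g <- tapply(kept$modification == "oglcnac", key, any)
  ukey <- names(has_p)
  cls <- ifelse(has_p & has_g, "crosstalk",
                ifelse(has_p, "phospho_only", "oglcnac_only"))
  first <- kept[!duplicated(key), , drop = FALSE]
  first <- first[match(ukey, paste(first$protein_id, first$position, sep = "\r")), ]
  classes <- data.frame(protein_id = first$protein_id,
                        position = first$position,
                        residue = first$residue,
                        class = unname(cls),
                        stringsAsFactors = FALSE)
  classes <- classes[order(classes$protein_id, classes$position), ]
  rownames(classes) <- NULL
  structure(list(sites = kept, classes = classes, rejected = rejected),
            class = "SiteCatalog")
}

#' @export
print.SiteCatalog <- function(x, ...) {
  tab <- table(x$classes$class)
  cat("SiteCatalog:", nrow(x$classes), "distinct sites on",
      length(unique(x$classes$protein_id)), "proteins\n")
  for (cl in c("crosstalk", "phospho_only", "oglcnac_only"))
    cat(sprintf("  %-13s %d\n", cl, if (cl %in% names(tab)) tab[[cl]] else 0L))
  if (nrow(x$rejected)) cat("  rejected rows:", nrow(x$rejected), "\n")
  invisible(x)
}

#' Class of a single site
#'
#' @param catalog A `SiteCatalog`.
#' @param protein_id,position Site coordinates (1-based position).
#' @return `"crosstalk"`, `"phospho_only"`, `"oglcnac_only"`, or `NA` if
#'   the site is not in the catalog.
#' @export
class_of <- function(catalog, protein_id, position) {
  m <- catalog$classes$protein_id == protein_id &
    catalog$classes$position == position
  if (!any(m)) return(NA_character_)
  catalog$classes$class[which(m)[1]]
}

#' Greedy sequence-identity redundancy reduction
#'
#' Proteins are sorted by decreasing length and greedily assigned to the
#' first cluster whose representative-founder shares global-alignment
#' identity at or above `identity_threshold`; otherwise they found a new
#' cluster. Identity is matched positions divided by alignment length
#' under Needleman-Wunsch with match +1, mismatch -1, gap -2. One member
#' per cluster is then drawn at random (seeded) as representative.
#'
#' @param proteins Named character vector of sequences.
#' @param identity_threshold Fraction in (0, 1]; default 0.7.
#' @param seed Integer seed controlling representative choice.
#' @return List with `representatives` (named character vector) and
#'   `clusters` (named integer vector: cluster index per protein).
#' @export
redundancy_reduce <- function(proteins, identity_threshold = 0.7, seed = 1L) {
  stopifnot(length(proteins) >= 1L,
            identity_threshold > 0, identity_threshold <= 1)
  ord <- order(-nchar(proteins), names(proteins))
  seqs <- proteins[ord]
  founders <- integer(0)          # index into seqs of each cluster founder
  assign_ <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    placed <- FALSE
    for (k in seq_along(founders)) {
      if (pairwise_identity(seqs[[i]], seqs[[founders[k]]]) >= identity_threshold) {
        assign_[i] <- k; placed <- TRUE; break
      }
    }
    if (!placed) { founders <- c(founders, i); assign_[i] <- length(founders) }
  }
  reps <- with_seed(seed, {
    vapply(seq_along(founders), function(k) {
      members <- which(assign_ == k)
      members[sample.int(length(members), 1L)]
    }, integer(1))
  })
  clusters <- setNames(assign_, names(seqs))[names(proteins)]
  representatives <- seqs[reps]
  list(representatives = representatives, clusters = clusters)
}

#' Global-alignment identity between two sequences
#'
#' Needleman-Wunsch with match +1, mismatch -1, linear gap -2; identity is
#' matched positions / alignment length.
#'
#' @param a,b Sequences (character scalars).
#' @return Identity fraction in \[0, 1\].
#' @export
pairwise_identity <- function(a, b) {
  r <- .nw_identity_cpp(a, b)
  if (r[["length"]] == 0) return(0)
  r[["matches"]] / r[["length"]]
}

#' Read protein-to-GO annotations
#'
#' @param path Annotation file. For `dialect = "tsv2col"` a two-column TSV
#'   (protein id, GO term id; a header line starting with `protein` is
#'   skipped). For `dialect = "gaf"` a GAF 2.x file: comment lines starting
#'   with `!` are skipped, protein id taken from column 2, term from
#'   column 5.
#' @param dialect `"tsv2col"` or `"gaf"`.
#' @return A `GOAnnotationMap`: list with `map` (named list protein ->
#'   character vector of terms) and `universe` (sorted distinct terms).
#' @export
read_go_annotations <- function(path, dialect = c("tsv2col", "gaf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (dialect == "gaf") {
    lines <- lines[!startsWith(lines, "!")]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    parts <- parts[lengths(parts) >= 5]
    pid <- vapply(parts, `[[`, "", 2L)
    term <- vapply(parts, `[[`, "", 5L)
  } else {
    lines <- lines[nzchar(lines)]
    if (length(lines) && grepl("^protein", lines[1], ignore.case = TRUE))
      lines <- lines[-1]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) < 2)
    if (length(bad)) stop("malformed annotation line ", bad[1])
    pid <- vapply(parts, `[[`, "", 1L)
    term <- vapply(parts, `[[`, "", 2L)
  }
  go_annotation_map(pid, term)
}

#' Build a GOAnnotationMap from parallel id/term vectors
#' @param protein_ids,terms Equal-length character vectors.
#' @return A `GOAnnotationMap` (see [read_go_annotations()]).
#' @export
go_annotation_map <- function(protein_ids, terms) {
  stopifnot(length(protein_ids) == length(terms))
  if (!length(protein_ids))
    return(structure(list(map = list(), universe = character(0)),
                     class = "GOAnnotationMap"))
  map <- lapply(split(terms, protein_ids), function(x) sort(unique(x)))
  structure(list(map = map, universe = sort(unique(terms))),
            class = "GOAnnotationMap")
}

#' Terms annotated to one protein
#' @param go A `GOAnnotationMap`.
#' @param protein_id Protein identifier.
#' @return Character vector of GO terms (empty if unannotated).
#' @export
go_terms_of <- function(go, protein_id) {
  go$map[[protein_id]] %||% character(0)
}
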