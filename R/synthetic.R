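#' Default simulation configuration
#'
#' The stated world the generator emulates: 600 single-site proteins
#' (40 cross-talk, 400 phospho-only, 160 O-GlcNAc-only, so the default
#' 10:1 and 2:1 training ratios are exactly attainable), 10
#' label-informative GO terms at flip probability eps = 0.15 among 1990
#' Bernoulli(0.1) noise terms, one planted motif (P at offset +3, 40%
#' prevalence among cross-talk sites), and 10-species ortholog MSAs with
#' higher conservation at the modified column than in its flanks.
#'
#' @param ... Overrides for any field.
#' @return A `SimulationConfig` list.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_crosstalk = 40L,
    n_phospho_only = 400L,
    n_oglcnac_only = 160L,
    length_range = c(61L, 120L),
    n_go_noise = 1990L,
    n_go_informative = 10L,
    eps = 0.15,              # informative-term flip probability
    go_noise_rate = 0.1,
    motifs = list(list(pattern = "[S]xxP", prevalence = 0.4)),
    n_species = 10L,
    site_conservation = 0.9, # P(keep reference letter) at modified column
    flank_conservation = 0.6,
    gap_rate = 0.02,
    mix_proteins = FALSE,    # crosstalk and negative sites share proteins?
    seed = 1L)
  over <- list(...)
  stopifnot(all(names(over) %in% names(cfg)))
  cfg[names(over)] <- over
  stopifnot(cfg$eps >= 0, cfg$eps < 0.5,
            all(vapply(cfg$motifs, function(m)
      m$prevalence >= 0 && m$prevalence <= 1, logical(1))))
  structure(cfg, class = "SimulationConfig")
}

#' Simulate proteins with planted PTM sites and motifs
#'
#' One site per protein (crosstalk and negative sites on disjoint
#' proteins, keeping protein-level GO features learnable). Residues are
#' i.i.d. uniform over the 20 amino acids except at planted motif
#' positions; every site center is S or T. Planted motifs are assigned
#' to cross-talk sites only, mutually exclusively, at the configured
#' prevalences.
#'
#' @param config A `SimulationConfig`.
#' @return List with `proteins` (named character vector), `catalog`
#'   (`SiteCatalog`), `sites` (site rows incl. class) and `truth`
#'   (planted-motif carriers).
#' @export
simulate_proteins <- function(config) {
  cfg <- config
  n_total <- cfg$n_crosstalk + cfg$n_phospho_only + cfg$n_oglcnac_only
  with_seed(cfg$seed, {
    lens <- sample_from(cfg$length_range[1]:cfg$length_range[2], n_total,
                        replace = TRUE)
    ids <- sprintf("SP%04d", seq_len(n_total))
    classes <- rep(c("crosstalk", "phospho_only", "oglcnac_only"),
                   c(cfg$n_crosstalk, cfg$n_phospho_only, cfg$n_oglcnac_only))
    # site placed away from termini when possible, on S or T
    seqs <- character(n_total)
    sitepos <- integer(n_total)
    motif_of <- rep(NA_integer_, n_total)
    # assign planted motifs to crosstalk proteins, mutually exclusive
    if (length(cfg$motifs) && cfg$n_crosstalk > 0L) {
      u <- runif(cfg$n_crosstalk)
      cum <- 0
      for (mi in seq_along(cfg$motifs)) {
        pv <- cfg$motifs[[mi]]$prevalence
        motif_of[seq_len(cfg$n_crosstalk)][u >= cum & u < cum + pv] <- mi
        cum <- cum + pv
      }
    }
    for (i in seq_len(n_total)) {
      chars <- sample(AA20, lens[i], replace = TRUE)
      # keep the site away from the termini and, when a motif is planted,
      # inside the span its fixed offsets require
      lo <- max(2L, min(21L, lens[i] - 1L)); hi <- lens[i] - 1L
      mot <- NULL
      if (!is.na(motif_of[i])) {
        mot <- parse_motif(cfg$motifs[[motif_of[i]]]$pattern)
        offs <- as.integer(names(mot$fixed))
        lo <- max(lo, 1L - min(0L, offs))
        hi <- min(hi, lens[i] - max(0L, offs))
        if (lo > hi) stop("planted motif does not fit protein ", ids[i])
      }
      pos <- sample_from(lo:hi, 1L)
      chars[pos] <- sample(c("S", "T"), 1L)
      if (!is.null(mot)) {
        if (mot$center %in% c("S", "T")) chars[pos] <- mot$center
        offs <- as.integer(names(mot$fixed))
        chars[pos + offs] <- unname(mot$fixed)
      }
      seqs[i] <- paste(chars, collapse = "")
      sitepos[i] <- pos
    }
    names(seqs) <- ids
    residue <- unname(substring(seqs, sitepos, sitepos))
    mods <- list(crosstalk = c("phospho", "oglcnac"),
                 phospho_only = "phospho", oglcnac_only = "oglcnac")
    rows <- do.call(rbind, lapply(seq_len(n_total), function(i) {
      data.frame(protein_id = ids[i], position = sitepos[i],
                 residue = residue[i], modification = mods[[classes[i]]],
                 stringsAsFactors = FALSE)
    }))
    catalog <- site_catalog(rows, seqs)
    list(proteins = seqs, catalog = catalog,
         sites = data.frame(protein_id = ids, position = sitepos,
                            residue = residue, class = classes,
                            motif = motif_of, stringsAsFactors = FALSE),
         truth = list(motif_carriers = ids[!is.na(motif_of)],
                      motif_index = motif_of))
  })
}

#' Simulate GO annotations with label-informative terms
#'
#' Informative term g_i is present on a protein with probability
#' 1 - eps when the protein carries a cross-talk site and eps otherwise;
#' noise terms are Bernoulli(`go_noise_rate`) independent of labels.
#'
#' @param config A `SimulationConfig`.
#' @param sim Output of [simulate_proteins()].
#' @return List with `go` (a `GOAnnotationMap`) and `truth` (character
#'   vector of informative term ids).
#' @export
simulate_go <- function(config, sim) {
  cfg <- config
  ids <- names(sim$proteins)
  is_ct <- sim$sites$class == "crosstalk"
  inf_terms <- sprintf("GO:INF%04d", seq_len(cfg$n_go_informative))
  noise_terms <- sprintf("GO:N%05d", seq_len(cfg$n_go_noise))
  with_seed(cfg$seed + 1L, {
    pid <- character(0); term <- character(0)
    for (g in inf_terms) {
      p_present <- ifelse(is_ct, 1 - cfg$eps, cfg$eps)
      has <- runif(length(ids)) < p_present
      pid <- c(pid, ids[has]); term <- c(term, rep(g, sum(has)))
    }
    for (g in noise_terms) {
      has <- runif(length(ids)) < cfg$go_noise_rate
      pid <- c(pid, ids[has]); term <- c(term, rep(g, sum(has)))
    }
    list(go = go_annotation_map(pid, term), truth = inf_terms)
  })
}

#' Simulate ortholog multiple sequence alignments
#'
#' For each protein, `n_species` rows: the reference row is the protein
#' itself; every other row keeps the reference letter with the
#' column-specific conservation rate (site column vs flanks), otherwise
#' substitutes uniformly among the other 19 letters; gaps replace
#' non-reference characters at `gap_rate`.
#'
#' @param config A `SimulationConfig`.
#' @param sim Output of [simulate_proteins()].
#' @return Named list of `OrthologAlignment` keyed by protein id;
#'   reference row id is `<protein>_ref`.
#' @export
simulate_msas <- function(config, sim) {
  cfg <- config
  with_seed(cfg$seed + 2L, {
    out <- lapply(names(sim$proteins), function(id) {
      seq <- sim$proteins[[id]]
      n <- nchar(seq)
      ref <- strsplit(seq, "", fixed = TRUE)[[1]]
      site <- sim$sites$position[sim$sites$protein_id == id]
      rate <- rep(cfg$flank_conservation, n)
      rate[site] <- cfg$site_conservation
      rows <- c(setNames(list(ref), paste0(id, "_ref")),
                lapply(seq_len(cfg$n_species - 1L), function(s) {
                  keep <- runif(n) < rate
                  chars <- ref
                  nk <- sum(!keep)
                  if (nk) chars[!keep] <- vapply(ref[!keep], function(r)
                    sample(setdiff(AA20, r), 1L), character(1))
                  gap <- runif(n) < cfg$gap_rate
                  chars[gap & !keep] <- "-"
                  chars
                }))
      names(rows)[-1] <- paste0(id, "_sp", seq_len(cfg$n_species - 1L))
      rows <- vapply(rows, paste, character(1), collapse = "")
      ortholog_alignment(rows, paste0(id, "_ref"))
    })
    names(out) <- names(sim$proteins)
    out
  })
}

#' Generate the full synthetic bundle
#'
#' @param config A `SimulationConfig` (default [sim_config()]).
#' @param msas Generate ortholog alignments too? (default TRUE)
#' @return List with `config`, `proteins`, `catalog`, `sites`, `go`,
#'   `alignments` and `truth` (informative GO terms, motif carriers).
#' @export
simulate_bundle <- function(config = sim_config(), msas = TRUE) {
  sim <- simulate_proteins(config)
  go <- simulate_go(config, sim)
  alignments <- if (msas) simulate_msas(config, sim) else NULL
  list(config = config, proteins = sim$proteins, catalog = sim$catalog,
       sites = sim$sites, go = go$go, alignments = alignments,
       truth = list(informative_terms = go$truth,
                    motif_carriers = sim$truth$motif_carriers))
}

#' Write a synthetic bundle to disk
#'
#' Emits FASTA, a site TSV, a GO TSV, one aligned FASTA per protein under
#' `msa/` plus a manifest, and a ground-truth JSON.
#'
#' @param bundle Output of [simulate_bundle()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(paste0(">", names(bundle$proteins), "\n", bundle$proteins),
             file.path(dir, "proteins.fasta"))
  write.table(bundle$catalog$sites, file.path(dir, "sites.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  map <- bundle$go$map
  go_df <- data.frame(
    protein_id = rep(names(map), lengths(map)),
    term = unlist(map, use.names = FALSE))
  write.table(go_df, file.path(dir, "go.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$alignments)) {
    msadir <- file.path(dir, "msa")
    dir.create(msadir, showWarnings = FALSE)
    manifest <- data.frame(protein_id = names(bundle$alignments),
                           file = paste0(names(bundle$alignments), ".afa"),
                           reference_id = vapply(bundle$alignments,
                                                 `[[`, "", "reference_id"))
    for (id in names(bundle$alignments)) {
      aln <- bundle$alignments[[id]]
      writeLines(paste0(">", names(aln$rows), "\n", aln$rows),
                 file.path(msadir, paste0(id, ".afa")))
    }
    write.table(manifest, file.path(dir, "msa_manifest.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(bundle$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
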