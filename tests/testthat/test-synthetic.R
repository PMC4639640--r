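test_that("simulated residues are uniform when no motif is planted", {
  cfg <- sim_config(n_crosstalk = 0, n_phospho_only = 1000,
                    n_oglcnac_only = 0, length_range = c(100L, 100L),
                    motifs = list(), seed = 2)
  sim <- simulate_proteins(cfg)
  chars <- unlist(strsplit(paste(sim$proteins, collapse = ""), ""))
  # drop the forced S/T site centers before testing uniformity
  counts <- table(chars)[ptmx:::AA20]
  counts["S"] <- counts["S"] - sum(sim$sites$residue == "S")
  counts["T"] <- counts["T"] - sum(sim$sites$residue == "T")
  p <- stats::chisq.test(as.vector(counts))$p.value
  expect_gt(p, 0.001)
})

test_that("site counts and determinism are exact", {
  cfg <- sim_config(n_crosstalk = 5, n_phospho_only = 7, n_oglcnac_only = 3,
                    seed = 4)
  sim <- simulate_proteins(cfg)
  expect_equal(sum(sim$catalog$classes$class == "crosstalk"), 5)
  expect_equal(sum(sim$catalog$classes$class == "phospho_only"), 7)
  expect_equal(sum(sim$catalog$classes$class == "oglcnac_only"), 3)
  sim2 <- simulate_proteins(cfg)
  expect_identical(sim$proteins, sim2$proteins)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_bundle(simulate_bundle(cfg), d1)
  write_bundle(simulate_bundle(cfg), d2)
  expect_identical(readLines(file.path(d1, "proteins.fasta")),
                   readLines(file.path(d2, "proteins.fasta")))
})

test_that("informative GO terms separate labels in the noiseless limit", {
  cfg <- sim_config(n_crosstalk = 20, n_phospho_only = 40,
                    n_oglcnac_only = 0, eps = 0, n_go_noise = 10,
                    n_go_informative = 3, seed = 5)
  sim <- simulate_proteins(cfg)
  g <- simulate_go(cfg, sim)
  is_ct <- sim$sites$class == "crosstalk"
  for (term in g$truth) {
    has <- vapply(names(sim$proteins), function(p)
      term %in% go_terms_of(g$go, p), logical(1))
    expect_identical(unname(has), is_ct)
  }
})

test_that("informative terms carry more label MI than noise at eps 0.15", {
  for (seed in 1:5) {
    cfg <- sim_config(n_crosstalk = 60, n_phospho_only = 140,
                      n_oglcnac_only = 0, eps = 0.15, n_go_noise = 50,
                      n_go_informative = 5, seed = seed)
    sim <- simulate_proteins(cfg)
    g <- simulate_go(cfg, sim)
    labels <- as.integer(sim$sites$class == "crosstalk")
    mi_of <- function(term) {
      x <- vapply(names(sim$proteins), function(p)
        term %in% go_terms_of(g$go, p), logical(1))
      empirical_mutual_information(as.integer(x), labels)
    }
    mi_inf <- vapply(g$truth, mi_of, numeric(1))
    noise_terms <- setdiff(g$go$universe, g$truth)
    mi_noise <- vapply(noise_terms, mi_of, numeric(1))
    expect_gt(mean(mi_inf), mean(mi_noise))
  }
})

test_that("at eps 0.5 informative terms carry no usable signal", {
  cfg <- sim_config(n_crosstalk = 50, n_phospho_only = 150,
                    n_oglcnac_only = 0, eps = 0.499, n_go_noise = 30,
                    n_go_informative = 3, seed = 6)
  sim <- simulate_proteins(cfg)
  g <- simulate_go(cfg, sim)
  labels <- as.integer(sim$sites$class == "crosstalk")
  mi_inf <- vapply(g$truth, function(term) {
    x <- vapply(names(sim$proteins), function(p)
      term %in% go_terms_of(g$go, p), logical(1))
    empirical_mutual_information(as.integer(x), labels)
  }, numeric(1))
  expect_lt(mean(mi_inf), 0.02)   # ~0 nats: indistinguishable from noise
})

test_that("MSA conservation rates match their closed-form expectation", {
  cfg <- sim_config(n_crosstalk = 1, n_phospho_only = 0, n_oglcnac_only = 0,
                    length_range = c(1000L, 1000L), motifs = list(),
                    n_species = 10L, flank_conservation = 0.6,
                    gap_rate = 0, seed = 7)
  sim <- simulate_proteins(cfg)
  alns <- simulate_msas(cfg, sim)
  aln <- alns[[1]]
  rcrs <- vapply(seq_len(1000), function(p) compute_rcr(aln, p), numeric(1))
  r <- cfg$flank_conservation
  # non-reference rows match w.p. r; the reference always matches
  expected <- (1 + (cfg$n_species - 1) * r) / cfg$n_species
  site <- sim$sites$position[1]
  expect_equal(mean(rcrs[-site]), expected, tolerance = 0.03)

  # full conservation limit
  cfg2 <- sim_config(n_crosstalk = 2, n_phospho_only = 2, n_oglcnac_only = 1,
                     site_conservation = 1, flank_conservation = 1,
                     gap_rate = 0, seed = 8)
  sim2 <- simulate_proteins(cfg2)
  alns2 <- simulate_msas(cfg2, sim2)
  for (id in names(alns2))
    expect_equal(compute_rcr(alns2[[id]],
                             sim2$sites$position[sim2$sites$protein_id == id]),
                 1.0)
  # determinism
  alns2b <- simulate_msas(cfg2, sim2)
  expect_identical(alns2, alns2b)
})

test_that("planted motifs do not fit an impossible protein", {
  cfg <- sim_config(n_crosstalk = 2, n_phospho_only = 0, n_oglcnac_only = 0,
                    length_range = c(5L, 5L),
                    motifs = list(list(pattern = "[S]xxxxxxxxxP",
                                       prevalence = 1)), seed = 9)
  expect_error(simulate_proteins(cfg), "does not fit")
})
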