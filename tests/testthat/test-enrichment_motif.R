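test_that("two-tailed Fisher p matches the fixed-margin enumeration oracle", {
  # worked table: fg 8/10 with term, bg 10/100 with term
  p <- fisher_two_tailed(8, 2, 10, 90)
  expect_equal(p, fisher_oracle(8, 2, 10, 90), tolerance = 1e-12)

  for (seed in 1:25) {
    tb <- withr::with_seed(seed, {
      N <- sample(8:60, 1)
      a <- sample(0:N, 1); b <- sample(0:(N - a), 1)
      c_ <- sample(0:(N - a - b), 1); d <- N - a - b - c_
      c(a, b, c_, d)
    })
    if (tb[1] + tb[2] == 0 || tb[3] + tb[4] == 0) next
    expect_equal(fisher_two_tailed(tb[1], tb[2], tb[3], tb[4]),
                 fisher_oracle(tb[1], tb[2], tb[3], tb[4]),
                 tolerance = 1e-12)
  }
})

test_that("enrichment tests only fg-annotated terms and applies the filters", {
  go <- go_annotation_map(
    c("A", "A", "B", "C", "D", "E", "F"),
    c("GO:X", "GO:Y", "GO:X", "GO:Z", "GO:Z", "GO:Z", "GO:W"))
  # GO:W annotates no fg protein -> untested
  res <- fisher_enrichment(c("A", "B"), c("C", "D", "E", "F"), go)
  expect_setequal(res$term, c("GO:X", "GO:Y"))
  # fg = bg -> ratio 1 everywhere, nothing passes
  res2 <- fisher_enrichment(c("A", "B", "C"), c("A", "B", "C"), go)
  expect_true(all(res2$ratio == 1))
  expect_false(any(res2$passes))
  # worked ratio: (8/10)/(10/100) = 8
  go3 <- go_annotation_map(
    c(sprintf("f%02d", 1:8), sprintf("b%03d", 1:10)),
    rep("GO:T", 18))
  res3 <- fisher_enrichment(sprintf("f%02d", 1:10), sprintf("b%03d", 1:100),
                            go3)
  expect_equal(res3$ratio[res3$term == "GO:T"], 8)
  # Bonferroni never decreases p; passing implies raw p < 0.05
  expect_true(all(res3$p_bonferroni >= res3$p_raw))
  expect_true(all(res3$p_raw[res3$passes] < 0.05))
})

test_that("motif strings round-trip through the parser", {
  for (s in c("Pxx[S]", "Txxx[S]", "[T]xxxxxxxxxP", "[S]", "RxRxx[S]xP")) {
    m <- parse_motif(s)
    expect_identical(motif_to_string(m$center, m$fixed), s)
  }
  m <- parse_motif("Pxx[S]")
  expect_identical(m$center, "S")
  expect_identical(m$fixed, c("-3" = "P"))
  expect_error(parse_motif("PxxS"), "center")
})

test_that("motif-x fixes a planted dominant position first", {
  fg <- random_windows(120, seed = 1)
  fg <- vapply(fg, function(w) plant_motif(w, parse_motif("[S]xxP")),
               character(1), USE.NAMES = FALSE)
  bg <- random_windows(4000, seed = 2)
  motifs <- motifx_extract(fg, bg, p_threshold = 1e-6, min_count = 20)
  expect_gte(length(motifs), 1)
  expect_identical(names(motifs[[1]]$fixed)[1], "3")
  expect_identical(unname(motifs[[1]]$fixed[1]), "P")
  expect_gte(motifs[[1]]$fg_matches, 20)
})

test_that("motif-x finds nothing when fg matches bg composition", {
  all_w <- random_windows(3000, seed = 3)
  fg <- all_w[1:150]; bg <- all_w
  motifs <- motifx_extract(fg, bg, p_threshold = 1e-6, min_count = 20)
  expect_length(motifs, 0)
  # fg below min_count is empty by definition
  expect_length(motifx_extract(all_w[1:5], bg), 0)
  expect_error(motifx_extract(random_windows(30, center = "S"),
                              random_windows(30, center = "T")), "mixed")
})

test_that("emitted motifs are stable when unrelated bg windows are removed", {
  fg <- random_windows(200, seed = 4)
  fg[1:120] <- vapply(fg[1:120], function(w)
    plant_motif(w, parse_motif("[S]xxP")), character(1), USE.NAMES = FALSE)
  bg <- random_windows(5000, seed = 5)
  m1 <- motifx_extract(fg, bg)
  # drop 20% of bg windows that do not carry the planted motif
  unrelated <- which(substring(bg, 14, 14) != "P")
  bg2 <- bg[-unrelated[seq_len(1000)]]
  m2 <- motifx_extract(fg, bg2)
  expect_identical(vapply(m1, `[[`, "", "pattern")[1],
                   vapply(m2, `[[`, "", "pattern")[1])
})

test_that("the motif pipeline filters occurrences by conservation", {
  # catalog with a strong planted motif on every crosstalk site
  cfg <- sim_config(n_crosstalk = 30, n_phospho_only = 60, n_oglcnac_only = 10,
                    motifs = list(list(pattern = "[S]xxP", prevalence = 1)),
                    seed = 11)
  sim <- simulate_proteins(cfg)
  go <- simulate_go(cfg, sim)$go

  # fully conserved alignments: nothing is filtered
  alns <- lapply(sim$proteins, function(s) {
    rows <- setNames(rep(s, 3), c("r", "a", "b"))
    ortholog_alignment(rows, "r")
  })
  res <- motif_pipeline(sim$catalog, sim$proteins, alns, go,
                        p_threshold = 1e-4, min_count = 10)
  expect_gte(length(res), 1)
  has_planted <- vapply(res, function(m)
    "3" %in% names(m$fixed) && m$fixed[["3"]] == "P", logical(1))
  expect_true(any(has_planted))
  hit <- res[[which(has_planted)[1]]]
  expect_true(all(hit$occurrences$conservation == 1))
  expect_true(all(hit$occurrences$kept))
  expect_setequal(hit$surviving_proteins,
                  unique(hit$occurrences$protein_id))
})
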