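# ptmx

Analysis and prediction of *in situ* O-GlcNAc/phosphorylation cross-talk
sites on serine and threonine residues.

O-GlcNAcylation and phosphorylation can compete for the exact same Ser/Thr
hydroxyl — negative, *in situ* cross-talk. `ptmx` is an R toolkit for
studying and predicting such doubly-modifiable sites from three ingredients:
protein sequences, experimentally determined PTM site tables, and
protein-level GO annotation. It is aimed at computational biologists who
have site catalogs from resources such as PhosphoSitePlus or dbOGAP and
want to (a) characterize cross-talk sites (conservation, GO enrichment,
sequence motifs) and (b) train classifiers that flag singly-annotated sites
likely to carry the second modification.

## What it computes

* **Conservation.** For a site at ungapped reference position *i* of an
  ortholog multiple alignment, the residue conservation ratio is
  `RCR = N_c / N_total`, where `N_c` counts rows carrying exactly the
  reference residue at the aligned column and `N_total` is the number of
  rows. The relative RCR (`rRCR`) is the mid-rank percentile of the site's
  RCR within the RCRs of its ±20-residue flanks; distributions are compared
  across site classes with a two-sample Kolmogorov–Smirnov test.
* **GO enrichment.** Native two-tailed Fisher exact test per term with
  Bonferroni correction; a term passes at fold-enrichment ratio > 4 and
  adjusted p < 0.05.
* **Motifs.** A motif-x-style iterative binomial position/residue fixation
  extracts overrepresented patterns around cross-talk sites (defaults
  p < 1e-6, ≥ 20 foreground occurrences), occurrences are filtered at motif
  conservation ≥ 0.4, and surviving proteins are tested for GO enrichment.
* **Classification.** Sites are encoded as 21-residue windows, one-hot over
  a 21-letter alphabet (20 amino acids + `*` terminus padding), giving 441
  binary features, concatenated with per-protein GO indicator bits. GO
  features are ranked by mRMR (Φ = D − R on plug-in mutual information,
  nats) and added one at a time to an RBF-kernel SVM (class-weighted C-SVC,
  solved by SMO — implemented in this package) under pooled 10-fold
  cross-validated AUC; the subset at the AUC maximum defines the final
  model. Performance is reported as Sn/Sp/Acc/Pre/MCC at high, medium, and
  low stringency (specificity > 0.95 / 0.90 / 0.85) plus ROC/AUC.
* **Synthetic truth.** A seeded generator produces proteins, site catalogs,
  GO annotation with label-informative terms, planted motifs, and ortholog
  MSAs with controlled column conservation, so the whole pipeline is
  testable without any database download.

Two classifier bases mirror the intended screening uses: `phos_based`
(cross-talk vs phospho-only sites, default negative:positive ratio 10:1)
and `glcnac_based` (cross-talk vs O-GlcNAc-only, 2:1).

## Worked example

```r
library(ptmx)

bundle <- simulate_bundle(sim_config(seed = 1), msas = FALSE)
ts     <- build_training_set(bundle$catalog, "phos_based", seed = 1)
ts
#> TrainingSet (phos_based): 40 positives, 400 negatives (ratio 10.00)

fm  <- assemble_features(ts, bundle$proteins, bundle$go)
dim(fm)                       # 440 x 2441: 441 sequence bits + 2000 GO bits
rk  <- mrmr_rank(fm[, -(1:441)], ts$labels, k = 500)
sum(bundle$truth$informative_terms %in% rk$feature_names[1:50])
#> 10                          # all planted informative terms recovered

folds <- stratified_folds(ts$labels, 10, seed = 1)
trace <- forward_select(fm[, 1:441],
                        fm[, -(1:441)][, rk$order[1:30]], ts$labels,
                        folds = folds,
                        cost_grid = 2^c(-1, 1, 3, 5),
                        gamma_grid = 2^c(-9, -7, -5, -3))
trace
#> SelectionTrace: baseline AUC 0.676; optimal AUC 1.000 at 27 GO features
```

The baseline (sequence-only) AUC of ≈ 0.68 reflects the weak sequence
signature of cross-talk sites; adding the first ten mRMR-ranked GO features
lifts pooled CV AUC by ≈ 0.32, after which the trace plateaus — functional
annotation, not sequence context, carries most of the signal.

The same pipeline is scriptable:

```sh
ptmx simulate --seed 1 --out bundle/
ptmx build-dataset --fasta bundle/proteins.fasta --sites bundle/sites.tsv \
     --go bundle/go.tsv --basis phos --ratio 10 --seed 1 --out features.tsv
ptmx rank --features features.tsv --k 500 --out ranking.tsv
ptmx evaluate --features features.tsv --seed 1 --out report.tsv
```

(`ptmx` is the launcher installed at `exec/ptmx` inside the package; call
`ptmx::ptmx_cli(c("simulate", ...))` from R for the same effect.)

## Layout

* `R/` — I/O and site classification, conservation, features, mRMR, SVM +
  evaluation, enrichment + motif-x, synthetic generator, CLI.
* `src/` — Needleman–Wunsch identity scorer and the SMO SVM solver.
* `tests/testthat/` — unit, property, and acceptance tests; brute-force
  oracles live in `helper-oracles.R`.
* `vignettes/ptmx-methods.Rmd` — model assumptions, parameter choices, and
  the limits of what the synthetic benchmarks establish.
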