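---
title: "ptmx: methods, assumptions, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ptmx: methods, assumptions, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptmx)
```

`ptmx` studies serine/threonine residues that can carry either a phosphate
or an O-GlcNAc moiety — *in situ* cross-talk sites, where the two
modifications compete for the same hydroxyl. This vignette explains the
statistical machinery, the parameters that matter, and the choices made
where the design was genuinely open. It states no empirical claim that the
package's tests and acceptance script do not themselves compute.

## Site classes and training sets

A site catalog partitions distinct (protein, position) pairs into
`crosstalk` (both modification types recorded at that exact position),
`phospho_only`, and `oglcnac_only`. Rows failing validation (position out
of bounds, residue letter disagreeing with the sequence, residue not S/T)
are rejected and counted, never silently dropped. Duplicate rows collapse
to one site: public PTM databases overlap heavily, and there is no
defensible weighting for "recorded twice".

Training sets take every cross-talk site as a positive and sample
negatives uniformly without replacement from one single-modification
class: phospho-only at a default negative:positive ratio of **10:1**
(phosphosites are plentiful) or O-GlcNAc-only at **2:1** (roughly the
abundance ratio of O-GlcNAc-only sites to cross-talk sites in curated
data). When the pool cannot satisfy the ratio, all negatives are used and
a warning records the achieved ratio — the contract is "ratio if
available", not silent rebalancing.

Redundancy reduction replaces a BLAST clustering step with a greedy,
dependency-free equivalent: proteins sorted by decreasing length, each
joining the first cluster whose founder shares global-alignment identity
≥ 0.7, identity being matched positions over alignment length under
Needleman–Wunsch with match +1, mismatch −1, linear gap −2. The
representative of each cluster is drawn with a caller-supplied seed,
because "pick one at random" is only reproducible if the generator is
pinned.

## Conservation: RCR and rRCR

For an ortholog alignment with `N_total` rows, the residue conservation
ratio of a site is `RCR = N_c / N_total`, `N_c` counting rows whose
character at the mapped column equals the reference residue *exactly*.
Three deliberate readings:

* S and T are **not** interchangeable. Counting T as conserving an S site
  would presuppose the modifiability equivalence the analysis is trying to
  measure; exact match is the conservative choice.
* Gap characters count in `N_total` but never in `N_c` — a deletion is
  non-conservation, not missing data.
* The reference row itself counts in both, so RCR ≥ 1/N_total.

The relative RCR asks whether the site is conserved *beyond its local
context*: compute RCR for every reference residue within ±20 positions,
drop the site itself, and take the mid-rank percentile
`(#below + 0.5·#equal) / #flanks`. Mid-ranking makes a uniformly conserved
region score 0.5 instead of an arbitrary extreme; excluding the site keeps
the comparison strictly site-vs-flanks. The full ±20 window (41 values,
site included) is returned alongside, and windows truncate at the termini
rather than erroring. Class-level comparisons use a two-sample KS test
with the asymptotic Kolmogorov p-value at effective size
`n_a·n_b/(n_a+n_b)`; flank distributions here have tens of values, where
the asymptotic form is adequate and exact small-sample enumeration is not
worth its cost.

Motif conservation — used by the motif filter below — is the mean RCR over
a motif occurrence's fixed positions, central residue included. The source
workflow prints no formula for this quantity; the mean is our stated
choice and is flagged as such in the function documentation.

## Enrichment and motifs

GO enrichment is a native two-tailed Fisher exact test: every term
annotating ≥ 1 foreground protein is tested on its 2×2 table, the
two-tailed p summing all fixed-margin tables no more probable than the
observed one (with a `1 + 1e-7` relative guard against floating-point
ties, the convention Fisher implementations share). Bonferroni correction
runs over the tested terms only. A term "passes" at fold-enrichment
ratio > 4 and adjusted p < 0.05.

Motif extraction reimplements the motif-x idea: at each step, for every
(offset ≠ 0, residue) pair, compute the binomial tail
`P[X ≥ k_fg]`, `X ~ Binomial(n_fg, f_bg)` with `f_bg` the residue's
frequency at that offset in the *current* background; fix the most
significant pair if p < 1e-6 and `k_fg ≥ 20` (the motif-x conventions —
the source states no parameters); restrict both window sets and repeat.
Emitted motifs have their matches removed from both pools before the scan
restarts. Runs are per central residue (S and T separately), and the
extraction background is every S/T-centered window of the input proteome,
since no background was named by the source. Occurrences with motif
conservation < 0.4 are dropped — **exactly 0.4 survives** — and proteins
with ≥ 1 surviving occurrence are enriched against the proteins carrying
cross-talk sites; a motif is flagged "potential functional" on any raw
p < 0.05, matching the looser screening intent of that step (the strict
ratio>4 + Bonferroni rule still appears per term in the output).

## Features and the classifier

Each site contributes a 21-residue window (±10; `*` pads beyond the
termini). Every position is one-hot over a fixed 21-letter alphabet — the
20 amino acids alphabetically, then `*` — giving 441 bits with exactly 21
ones. The published description of this encoding ("100⋯0 for Cys, 010⋯0
for Ser") does not pin a full letter ordering, so ours is alphabetical and
documented; any fixed ordering is equivalent for the classifier.
Non-standard letters map to `*` with a warning. GO features are binary
indicators in lexicographic universe order, taken from the supplied
annotation file rather than any hard-coded dimension, because the GO term
count is annotation-release-specific.

mRMR ranks GO features greedily: step 1 maximizes I(x; c); step *t*
maximizes `I(x; c) − (1/|S|) Σ_{j∈S} I(x; x_j)` — the incremental form of
Φ = D − R, which is the standard tractable surrogate for the set-level
criterion (exact maximization is combinatorial). Mutual information is the
plug-in estimate on observed cells in nats; the defining integral reduces
to this sum because every feature here is a 0/1 indicator, and any change
of log base rescales all terms equally, leaving every argmax — hence the
ranking — unchanged (this is tested). Ties break to the lower column
index. Pairwise MI against all candidates is computed from a single matrix
product per step, so ranking 500 of ~2000 features over ~500 samples takes
seconds.

The classifier is a class-weighted C-SVC with RBF kernel. No SVM library
is available in the target environment, so the solver is implemented in
`src/svm_smo.cpp`: SMO with maximal-violating-pair working-set selection,
per-class box constraints, stopping tolerance 1e-3, and a Platt sigmoid
fitted on the training decision values so predictions are probabilities in
(0, 1) — any monotone score would do for ROC and thresholding; the sigmoid
only serves interpretability of the reported "possibility". One weighting
subtlety: the source text says the *negative* class weight was set to the
negative/positive ratio, which would amplify the imbalance rather than
correct it. The default here weights the **positive** (minority) class by
that ratio — the standard balancing the sentence almost certainly intends
— and `weight_mode = "negative"` reproduces the literal reading.

Wrapper selection: hyperparameters (cost, gamma) are grid-searched once on
the sequence-only baseline (default grids `2^-5..2^15` / `2^-15..2^3`,
step `2^2`; ties to the smaller pair) and then held fixed while ranked GO
features are added one at a time, each step scored by pooled 10-fold CV
AUC on a fixed stratified fold assignment. Re-tuning at every one of up to
500 steps would multiply cost by the grid size for no stated benefit; a
`retune_every` option exists for users who disagree. AUC is pooled across
folds (single ROC from all out-of-fold scores) rather than fold-averaged,
matching the reporting of single metric values per configuration.

Stringency reporting: for each specificity floor (high 0.95, medium 0.90,
low 0.85) the threshold maximizes sensitivity subject to Sp **strictly
above** the floor ("Sp > 0.95" is read literally), scanning the descending
unique scores with `Inf` included so the all-negative operating point
(Sp = 1) always exists. Metrics follow the usual confusion-matrix
definitions; MCC is defined as 0 when any denominator factor vanishes.

## The synthetic world

The generator emits a stated world, not a tunable dial; its defaults are
fixed and the tests are written against them:

* **600 sites** on 600 single-site proteins of length 61–120: 40
  cross-talk, 400 phospho-only, 160 O-GlcNAc-only — chosen so the default
  10:1 and 2:1 ratios are *exactly* attainable (440- and 120-instance
  training sets).
* **GO**: 10 informative terms present with probability 1 − ε on
  cross-talk proteins and ε otherwise, ε = 0.15, among 1990 Bernoulli(0.1)
  noise terms. Cross-talk and negative sites sit on disjoint proteins by
  default (GO is protein-level, so mixing would leak labels across
  classes); `mix_proteins` exists for stress tests.
* **Motifs**: one planted pattern (`[S]xxP`, prevalence 0.4 among
  cross-talk sites) by default; recovery benchmarks plant two (40%/30%).
* **MSAs**: 10 rows (ten species is the scale of the real ortholog
  pipeline); non-reference rows keep the reference letter with probability
  0.9 at the modified column and 0.6 in the flanks, substituting uniformly
  among the other 19 letters otherwise, with 2% gaps. The 0.9/0.6 split
  makes sites visibly but not perfectly conserved — typical of functional
  residues — and gives rRCR a non-degenerate reference distribution. Under
  this scheme a column's expected RCR is `(1 + (n−1)·r)/n`, which the
  tests check in closed form.

What a green run does establish: the encoding contract, the exactness of
the statistics against brute-force oracles, that mRMR recovers planted
informative terms (≥ 8/10 in the top 50 across seeds), that the wrapper
lifts pooled CV AUC from a weak sequence baseline (≈ 0.68) to ≥ 0.85 with
a steep-rise-then-plateau trace, that label permutation collapses AUC to
chance, and that motif-x recovers planted motifs with their exact fixed
positions. What it does **not** establish: real-data performance. The
generator's i.i.d. residues, single-site proteins, flat GO structure (no
DAG, no annotation bias), and noise-free site labels are all kinder than
reality; headline numbers from curated human data (e.g. AUCs near 0.9)
depend on that specific data and are deliberately not asserted anywhere in
this package.

## Numerical and degenerate-input choices

* Alignment identity uses traceback counts; ties in the DP prefer
  diagonal, then up, then left, so identity is deterministic.
* `0·log 0 ≡ 0` throughout MI; Fisher and binomial tails use `dhyper` /
  `pbinom` rather than hand-rolled factorials.
* The SMO intercept averages `−y·G` over free support vectors, falling
  back to the feasible-interval midpoint when none is free.
* Degenerate fits (all rows identical) warn and proceed; single-class
  labels error everywhere a second class is required.
* All randomness flows through explicit seed arguments; internal seeding
  never perturbs the caller's RNG state (`.Random.seed` is restored).

## Scaling choices in the shipped tests

The acceptance tests and `scripts/acceptance.R` compute the wrapper trace
over the top **30** ranked GO features with a coarse 4×4 cost/gamma grid.
On this generator the trace plateaus within ~15 features, so the
assertions (optimal AUC ≥ 0.85, ≥ baseline + 0.05, steep rise over the
first 10 features) are unaffected while the run stays within a
single-CPU, few-minute budget; the full 500-step trace is available by
passing the full ranking to `forward_select`.

## Known limitations

* The redundancy reducer is O(clusters × proteins) pairwise alignments;
  for proteome-scale inputs a k-mer prefilter would be needed.
* Exact small-sample KS p-values are out of scope (D is exact; p is
  asymptotic).
* The motif-enrichment background and motif-x parameters follow stated
  conventions, not a published parameterization; Table-level motif lists
  from curated data are dataset-specific and not reproduced here.
* Platt calibration is fitted on training decision values, not an inner
  CV; probabilities are monotone-correct but can be optimistic near the
  margins.
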