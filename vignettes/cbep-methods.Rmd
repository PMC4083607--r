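---
title: "Methods: sequence-based conformational epitope prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence-based conformational epitope prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures behind `cbep`, the
choices that were genuinely open when it was built, and what its tests do
and do not demonstrate.

## The problem

A conformational B-cell epitope is a set of antigen surface residues,
discontinuous in sequence but proximate in space, that an antibody
recognizes. Predicting them from sequence alone is a doubly hard residue
classification problem: the positive class (antigenic determinant
residues) is around 6% of residues, and a residue-level prediction is not
yet an epitope — the called residues still have to be grouped into
spatially coherent candidate sites. `cbep` addresses both parts:
a cost-sensitive boosted SVM ensemble for the imbalanced residue
classification, and a threshold-driven divisive spatial clustering for the
grouping.

## Feature encoding

Each residue is represented by five feature classes, four of them windowed
and one chain-global. With window size N (odd; default 11, selected in the
source work by comparing windows 7–15), the total width is
20N + 3N + N + 6N + 420; at N = 11 that is 220 + 33 + 11 + 66 + 420 = 750.

* **Evolutionary profile (20N).** Raw blastpgp PSSM scores x are mapped
  through the logistic function 1/(1 + e^(-x)), so every value lies
  strictly in (0, 1).
* **Secondary structure (3N).** PSIPRED helix/coil/strand probabilities.
* **Disorder (N).** DISOPRED binary disorder status.
* **Physicochemical scales (6N).** Six per-residue scales: Parker
  hydrophilicity, Karplus–Schulz flexibility, Emini surface accessibility,
  Grantham polarity, Janin accessible surface area and Chou–Fasman turn
  propensity, each min–max normalized to [0, 1]. The exact tables live in
  `inst/extdata/physicochemical_scales.tsv` and can be swapped; the source
  work cites these properties without printing values, so the standard
  published tables are used. (Its prose mentions a 3 × N physicochemical
  block, but six properties and the printed 750 total force 6 × N.)
* **Dipeptide composition (420, chain-global).** 20 amino-acid
  frequencies (counts over the chain length) followed by the 400 ordered
  dipeptide frequencies AA, AC, ..., YY over all overlapping pairs. This
  block is identical for every residue of a chain.

Windows are padded with (N−1)/2 pseudoterminal positions at each end so
terminal residues get full windows; pads are zero-valued. The source work
specifies zero pads for the evolutionary block only; `cbep` extends the
zero pad to every block for uniformity. Non-standard letters (B, Z, X, U,
O) are kept in the sequence — so indexing stays aligned with external
profile files — but are skipped in dipeptide counting and score 0 on every
physicochemical scale. The dipeptide denominator is the number of
countable pairs (L−1 for clean chains); a chain with no countable pair
gets an all-zero dipeptide part. Amino-acid composition uses the whole
chain length as denominator.

## Feature selection

Features are ranked by the classical per-feature Fisher discriminant ratio
(μ₊ − μ₋)² / (σ₊² + σ₋²) — the linear special case of the Fisher–Markov
family of class-difference selectors; the full Markov-random-field
optimization of that selector is out of scope, and the scorer is pluggable
(`rank_features(scorer = ...)`). Ties break toward the lower original
column index so the ranking is deterministic and sample-order invariant.
Degenerate zero-variance features score +Inf when the class means differ
(they separate perfectly) and 0 otherwise.

Incremental feature selection (IFS) then evaluates growing ranked prefixes
Set_i = {feature_1, ..., feature_i} and keeps the prefix maximizing the
evaluator's score, smallest prefix on ties. Evaluating all 750 prefixes
with the full ensemble under per-chain cross-validation is cluster-scale
work, so `incremental_feature_selection()` accepts a prefix `stride` and
defaults to a fast evaluator (stratified k-fold AUC of a single SVM,
`make_svm_cv_evaluator()`); passing stride 1 and an evaluator wrapping
`csboost()` + `loocv()` reproduces the full protocol.

## Cost-sensitive boosting

Training samples are triples (l, x, c): label l ∈ {−1, +1}, feature vector
x, and a cost item c — `cost_fn` for positives and `cost_fp` for negatives
with `cost_fn > cost_fp` (defaults 4 : 1; 5 : 1 is the alternative profile
tuned on unbound-structure data). The ensemble is boosting by weighted
resampling: the sample-weight distribution starts proportional to the cost
items; each round draws a bootstrap subset of full training size, fits an
RBF SVM (defaults C = 32, γ = 0.003022; the unbound-style profile uses
C = 8, γ = 0.000068), and computes the cost-weighted error
ε = Σ_mis c·D / Σ c·D with round weight α = ½·ln((1−ε)/ε).

The precise weight update was an open choice (the source pseudocode is a
figure); `cbep` uses the AdaC2-family update

    D ← D · c^[misclassified] · exp(−α · l · h) / Z,

which matches every textual constraint — costs mark sample importance,
misclassified samples gain weight, and the gain is amplified by the
sample's cost — and collapses to textbook AdaBoost when all costs are 1
(verified against an independent AdaBoost loop in the tests). Rounds with
ε ≥ 0.5 are resampled up to 5 times, then training stops early with the
rounds completed. The round count k is not stated in the source; the
default is 10.

Scoring fuses the per-round SVM decision values (signed margins, not
probabilities): each is Z-score normalized with the mean/sd recorded on
the full training set at training time, squashed with tanh into (−1, 1),
and averaged with α weights (a uniform average is available via
`fusion = "uniform"`). A degenerate round with zero score sd contributes
tanh(0) = 0. Classification is the sign of the fused score (threshold 0,
configurable).

Two practical consequences of this fusion are worth knowing. First,
Z-centering places the effective decision boundary near the mean training
margin, which on heavily imbalanced data is a liberal threshold: held-out
sensitivity is high and specificity moderate, and downstream cluster
counts exceed the observed epitope counts, which depresses V_site/V_p at
the default threshold. Second, a uniform shift of the decision boundary —
which is the main first-order effect of raising the positive cost — is
largely absorbed by the same centering, so under the generator's default
(clearly separable) conditions the sensitivity-versus-cost curve sits at
its ceiling and the non-decreasing cost property holds with ties rather
than with a visible rise. The cost items still shape the weight dynamics
and subset composition across rounds.

## Spatial clustering

R_avg is the mean distance from annotated antigenic residues to the
centroid of their epitope (about 19 ± 2 Å on the benchmark antigen sets),
and the clustering threshold is T = α · (2 × R_avg) with α = 1.1, giving
the default T = 41.8 Å. `compute_r_avg()` recomputes R_avg from any
annotated, coordinate-bearing antigen set.

The clustering itself is divisive, matching the one-cluster-start,
threshold-split scheme of the source figure: all called residues start in
one cluster; while any cluster's diameter — the maximum pairwise C-alpha
distance, the stricter of the two plausible readings (the alternative,
distance to center, is not used) — exceeds T, that cluster is bisected by
2-means on the coordinates (best of 10 seeded restarts; a two-point
cluster splits trivially). Termination guarantees every output cluster
satisfies the diameter bound exactly; clusters are reported largest first,
ties by smallest member index, and singletons are legal (no minimum size
is imposed by default). An agglomerative complete-linkage backend cut at
height T is provided for comparison — complete linkage shares the
diameter-bound property. The residue representative point is the C-alpha
atom.

## Evaluation

Residue level: ACC, SN, SP and F from the confusion counts at the score
threshold, and AUC as the midrank (Wilcoxon) statistic — equal to the
all-pairs comparison with ties counted half, which the tests verify
against a brute-force oracle. Metrics with zero denominators and AUCs of
single-class chains are reported as `NA` rather than coerced.

Epitope level: predicted clusters are matched one-to-one to observed
epitopes greedily by descending coverage |cluster ∩ epitope| / |epitope|;
a pair counts only at strictly more than 30% coverage. V_site is matched
pairs over predicted clusters, pooled over the evaluation set; V_p is the
fraction of antigens with every epitope matched *and* predicted count
equal to observed count. Antigens with no predictions count as incorrect
and contribute nothing to the V_site denominator. Greedy one-to-one
matching is a documented choice — the source defines no many-to-one rule.

Cross-validation is leave-one-ANTIGEN-out: each chain is held out in
turn, the ensemble retrains on the rest, and performance is the unweighted
mean of per-chain AUCs (matching the "mean AUC" convention of this
field's benchmarks), with pooled residue metrics reported alongside for
transparency since the pooled-versus-averaged convention is ambiguous in
the source.

## Synthetic data

The generator emulates the statistical shape of the benchmark antigen
sets so every stage runs offline:

* **Geometry.** Self-avoiding random-walk backbones with 3.8 Å
  consecutive C-alpha spacing, a 4 Å exclusion radius and mild directional
  persistence (0.6) so chains extend far enough to host separated patches.
* **Epitopes.** 1–3 patches per chain, planted as all residues within
  9.5 Å of seed residues that are pairwise ≥ 50 Å apart — well beyond the
  41.8 Å threshold, so planted patches are recoverable by construction.
  Draws are retried until the positive fraction lands within ±50% of the
  6% target.
* **Profiles.** The class signal is injected at the raw-profile level,
  not into feature vectors, so the entire encoding path is exercised:
  positives get a mean shift of `class_effect_size` (in units of the
  2-point PSSM score sd; default 2, a clearly separable regime — 0 is the
  null control) on 8 of the 20 PSSM columns, a coil-tilted Dirichlet for
  secondary structure, and an elevated disorder rate. Everything is
  written in the blastpgp / PSIPRED / DISOPRED / PDB dialects and read
  back through the package's parsers; numeric profiles are emitted at the
  file formats' precision so write-then-read is the identity.

What the generator does *not* emulate: real protein folds, sequence–
structure consistency, evolutionary correlation structure in PSSMs, or
surface/buried geometry. Passing tests therefore demonstrate that the
pipeline's machinery is correct and behaves as designed under controlled
imbalance and separability — not that a given AUC will transfer to real
bound/unbound benchmark data.

## Numerical choices and problem sizes

All randomness flows through explicit `seed` arguments (per-fold and
per-chain seeds are derived from the root seed); identical seeds and data
reproduce identical models, scores and clusters. Score ties in ranking
break by column index, cluster-order ties by smallest member, matching
ties by epitope then cluster id. kmeans bisection uses 10 restarts;
boosting rounds retry resampling at most 5 times; the self-avoiding walk
retries directions 100 times and restarts up to 50 times.

The shipped tests and the acceptance script run the pipeline at desk
scale, chosen to keep the full suite in minutes on one CPU while leaving
every property measurable: 5–8 antigens of 100–250 residues per dataset,
boosting rounds 3–4 in resampling-heavy sweeps (10 for the single
benchmark run), 100 replicates for clustering recovery, and 10 seeds for
the cost sweep and the null/strong signal controls.

## Known limitations

* The Z-centered fusion makes threshold 0 a liberal operating point (see
  above); epitope-level V_site/V_p at that threshold are correspondingly
  modest and the threshold may warrant tuning per application.
* Under the null-signal control the per-chain AUC distribution is
  heavy-tailed — window overlap correlates the scores of neighbouring
  residues, so the few positive patches behave like 1–3 effective
  positives per chain.
* The Fisher-ratio ranking scores features marginally; correlated blocks
  (e.g. neighbouring window offsets) can occupy many top ranks jointly.
* PDB parsing handles single-model, single-altloc ATOM/CA records;
  mmCIF and NMR multi-model files are out of scope.
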