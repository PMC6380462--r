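---
title: "Disease-state discovery from toxicogenomic cohorts: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disease-state discovery from toxicogenomic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`toxds` implements an unsupervised analysis of repeated-dose toxicity
cohorts: it calls discrete disease states from physiology and
histopathology, characterizes them with defined statistics, follows them
over time, and models whole-body weight loss through secreted-factor
proxies. This vignette is the package's own account of the models, the
tunable parameters, the numerical choices, and what the accompanying
tests do and do not establish.

## The unit of analysis

Everything operates on *conditions* — one (compound, dose level, time
point) cell of the experimental grid, with animal replicates averaged
first (arithmetic mean over non-missing values; a condition missing all
replicates for a parameter stays missing and is flagged). The canonical
grid has eight time points: 3–24 h after a single dose, 4–29 days of
daily dosing.

## Normalization

Physiology parameters arrive in incomparable units, so each parameter is
centered and divided by its interquartile range across all conditions.
Quantiles use linear interpolation between order statistics (R's type 7),
recorded so results are bit-reproducible. Centering defaults to the
cohort mean; a vehicle-matched mode (subtract the same-compound,
same-time control condition) is available because the two conventions
appear interchangeably in practice and differ only by a per-parameter
shift. Constant parameters are rejected by name rather than silently
producing infinities.

Histopathology curation compares, for each (tissue, phenotype,
topography, grade) tuple, the number of vehicle versus compound-treated
animals showing it. The package keeps a tuple when
`n_vehicle / n_compound < r0`, where `r0` is the vehicle-to-treated
animal ratio of the whole project — the null expectation for a finding
unrelated to treatment. This is the *compound-enrichment* reading: keep
what is over-represented under treatment. The opposite comparator ships
as an option (`keep_if = "gt"`) because the procedure can defensibly be
stated in either direction; the default follows the stated purpose of
retaining findings the toxins induced. Note the threshold sits exactly
at the null expectation, so ~half of truly treatment-independent tuples
survive by chance when counts are small — an inherent property of the
rule, visible in the synthetic cohort.

## Calling disease states

The discovery loop is: Pearson distance (`1 − r` between condition
profiles) → t-SNE → severity smoothing → DBSCAN on the severe subset →
consensus over `n_runs` seeded repetitions → size/compound filter.

*Severity* is the number of distinct called phenotypes per tissue.
Because expert histopathology misses low-grade changes and scores few
sections per animal, raw severity is smoothed over the embedding: a
Nadaraya–Watson estimator built from two binned Gaussian kernel surfaces
(severity-weighted over unweighted) on a regular grid, read back by
bilinear interpolation. The bandwidth defaults to a normal-reference
rule per axis; the grid has 101 nodes per axis, and the binned estimate
agrees with the direct kernel regression to within 5 % when the
bandwidth spans a few grid cells (tested against an unbinned oracle).
Conditions in empty neighborhoods get severity 0 rather than 0/0.

Tunables that matter, with defaults:

| parameter | default | rationale |
|---|---|---|
| `perplexity` | 30 | the common t-SNE default; auto-shrunk with a warning when `n ≤ 3·perplexity` |
| `min_pts` | 5 | standard DBSCAN core-point count for 2-D maps |
| `eps` | per-run knee of the sorted 5-NN distance curve | adapts to each map's scale; the consensus absorbs per-run noise |
| `severity_threshold` | 0.5 phenotype-equivalents | half a phenotype of smoothed evidence; deliberately permissive, the consensus and filters do the pruning |
| `n_runs` | 100 (25 in the bundled analyses) | stochastic embeddings differ run to run; co-association frequencies stabilize well before 100 runs |
| `min_size`, `min_compounds` | 20, 2 | a state should be reachable by several conditions and more than one compound to support downstream statistics |

The knee is the point of maximum gap between the sorted k-NN distance
curve and its end-to-end chord (the curve runs below the chord for these
island-plus-scatter maps).

*Consensus.* Each run yields a labeling with noise. The co-association
matrix `M_ij` is the fraction of runs in which conditions i and j share
a non-noise cluster; consensus clusters come from average-linkage
hierarchical clustering of `1 − M` cut at 0.5 (i.e. pairs together in
at least half the runs), and each condition's *likelihood* is its mean
co-association with the other members of its consensus cluster, with
likelihood < 0.5 relabeled non-state. This particular consensus was
chosen because it is deterministic given the runs, yields likelihoods in
[0, 1] with a direct interpretation, and is checkable against an
exhaustive-partition oracle (the partition minimizing
`Σ|M_ij − same(i,j)|`) at small n — the test suite does exactly that for
n ≤ 8, R ≤ 3. Average linkage is monotone; tiny floating-point height
inversions are clamped before cutting. After the size/compound filter,
surviving clusters are renumbered by descending size (ties by first
appearance) and likelihoods recomputed against the final clusters —
historical state numberings are not reproducible and no meaning attaches
to the ids.

## Characterization statistics

Physiology deviation uses the unpaired two-sided Wilcoxon rank-sum test
of each state against the pooled non-state conditions, BH-adjusted over
the whole state × parameter grid, reported as signed log q
(`sign(Δmedian) · (−log10 q)`, threshold 1e-10). `stats::wilcox.test`
supplies exact p-values at small n and the continuity-corrected normal
approximation otherwise; the suite verifies exact agreement with full
enumeration for every achievable statistic up to n = 12. Histopathology
and compound-class enrichment are one-sided hypergeometric
(`stats::phyper`), restricted — for histopathology — to conditions with
at least one observation; enrichment tests carry sign +1 only, since
depletion is not scored. Class counting defaults to the condition level
with a compound-level mode, as either unit is defensible.

The transcriptome classifier is an elastic-net logistic model
(`glmnet`, mixing 0.5) with class weights reciprocal to the
*training-fold* class sizes, stratified 10-fold splits repeated 10
times, and out-of-fold (prevalidated) probabilities averaged across
repeats before one pooled AUROC. Computing weights per training fold is
what makes the prevalidation property exact: flipping a held-out label
cannot change that sample's own prediction, and the suite tests this
literally. The regularization strength is chosen by an internal
cross-validation maximizing AUROC, taking the strongest penalty within
one standard error of the best — the standard parsimony rule, which
keeps null-like fits close to the intercept and damps selection noise.
The inner loop is a lean reimplementation of the usual cross-validated
path search (the model engine remains glmnet) because the pipeline fits
hundreds of models per classifier and the stock wrapper spends most of
its time in assessment bookkeeping. Chance level comes from rerunning
the identical procedure on randomly drawn pseudo-states of the same
size; with 60-vs-240 designs the per-draw null AUROC spread is about
0.065, dominated by dataset-level spurious correlations no classifier
can avoid, so individual draws in the low 0.6s are expected.

## Pathway activity

The per-condition enrichment score is the classic unweighted running-sum
(KS) statistic: genes ranked by their expression change (descending,
ties broken by gene id for determinism), `+1/|S|` on set members,
`−1/(N−|S|)` otherwise, score = the walk value of maximal absolute
deviation. A weighting exponent is exposed but defaults to 0. The
production path computes the walk only at member positions; on exact
|max| ties both paths take the earliest walk step, with a 1e-12
tolerance so floating-point noise cannot flip the sign. Sets need ≥ 10
measured genes to be scored.

The state-level activity score is `sign(Δmedian) · (−log10 p)` from a
two-sample rank-sum test of the state's per-condition scores against the
non-state pool, deliberately *unadjusted*: gene-set collections are
highly redundant, so the package instead uses the strict cut
`|score| ≥ 5` (p ≤ 1e-5) to call a pathway changed. States are
clustered on their significant-activity columns with 1 − Spearman and
complete linkage; each pathway maps to the unique dendrogram node whose
leaf set equals the states sharing its direction — a leaf for an
exclusive pathway, the root for a universal one, and *unassigned* both
for patterns matching no clade and for pathways significant in both
directions across states (double-mapping mixed patterns would make node
summaries ambiguous).

## Dynamics

Sequences are read per (compound, dose) across the eight time points;
death truncates a sequence (dead time points join the bookkeeping but
never the transitions), non-state interludes are skipped, consecutive
repeats collapse, and a state re-entered after a gap contributes no
edge — transitions are meant to capture movement between states, not
persistence or measurement gaps. Edges supported by a single compound
are omitted. The suite checks graph equality on hand-computed fixtures
and invariance to non-state padding.

## Whole-body models

Cumulative expression is the trapezoidal AUC over the repeated-dose days
{1, 4, 8, 15, 29}; hour-scale single-dose points are excluded since the
outcome is the day-29 weight. The Igf1 latent model has one latent
activity per tissue measured by four indicator genes (first loading
fixed at 1 for identification, latents freely correlated) and a
structural regression of body weight on both latents. It is fit by
maximizing the multivariate-normal likelihood of the sample covariance
with L-BFGS-B: latent covariance through its Cholesky factor, residual
standard deviations on the log scale with a 1e-5 floor (which keeps the
zero-measurement-noise limit well-posed — the sample covariance may be
singular there and is never inverted). Starting values are
method-of-moments: triad estimates of the latent variances
(`S21·S31/S32`), loadings from covariances with the reference
indicator, structural coefficients from the 2×2 normal equations of the
reference indicators — exact in the noiseless limit, which is why that
limit recovers the coefficients to six decimals. Standard errors come
from the inverse observed information at the optimum and Wald p-values
from the normal reference. Complete-case analysis throughout; fits with
fewer than 30 complete cases are refused.

The Gdf15 model is ordinary least squares of daily food consumption on
liver and kidney Gdf15 expression, pooled and with a stratum ×
expression interaction; strata under 3 samples are excluded with a
warning, and a collinearity guard rejects degenerate covariate pairs.

## The synthetic cohort

The generator emulates the structure the analysis assumes: a full
compound × dose × time grid with vehicle arms per compound/time,
quintuplicate physiology animals and triplicate expression profiles,
planted states defined by disjoint five-parameter shifts (3 IQR units by
default) switching on at the fourth time point for high doses, planted
per-state histopathology phenotypes (per-animal rate 0.6) over a
three-phenotype spontaneous background (rate 0.01 per animal), planted
pathway shifts (±2 log2 units) in each state's tissue, and a planted
latent-factor / regression structure for the whole-body layer
(`l = 0.8`, `k = 0.2` by default). Noise is Gaussian on the normalized
scales — the simplest model consistent with the rank-based downstream
statistics. Treated conditions additionally carry a per-condition
biological expression effect (sd 1): without it the only condition-level
expression signal would be the shared subtracted-vehicle noise, which
correlates same-vehicle deltas and visibly miscalibrates the rank-sum
null. Background histopathology is deliberately confined to a few
common phenotypes: the curation rule thresholds at the null expectation,
and a diffuse many-phenotype background would leak half of itself
through curation at small counts.

What passing tests show — and what they do not. Recovery of the planted
partition (ARI ≥ 0.8, in practice ≈ 1.0 at the default effect size)
shows the pipeline's stages compose correctly and that the consensus
machinery finds well-separated states; it does not show that real
cohorts, whose states overlap, drift with time, and share parameters,
are equally recoverable. Likewise the liver classifier is perfect on
liver-planted states and at chance for kidney-planted ones because the
generator puts each state's transcriptome signal only in its own
tissue; real states leave cross-tissue traces.

## Problem sizes used by the test suite

The bundled analyses and the acceptance checks use the generator's
default cohort (600 treated conditions, 4 states, 25 consensus runs);
null calibration uses 1,000 random 20-gene sets over a 4,000-gene
universe (so sets overlap sparsely, in proportion to a ~900-set
collection over a ~30,000-gene array); the classifier checks use 300
conditions × 300 genes with a 60-member state and 40 permutation draws;
latent-model coverage uses 100 replicates at n = 300. Two invariants
run at reduced size: consensus stability is checked at 12 vs 24 runs on
a 300-condition cohort, and the monotonicity of recovery in effect size
on an 8-compound cohort over three seeds.

## Known limitations

Cluster ids carry no semantics; naming states clinically requires a
human reading of the profiles. The curation threshold equals the null
expectation, so weak-count tuples pass at coin-flip rates. Activity
p-values inherit whatever dependence exists between conditions (shared
vehicle arms, repeated compounds); the strict `|score| ≥ 5` cut is the
mitigation, not a correction. The latent model assumes linear loadings
and Gaussian errors, and its Wald inference is asymptotic. The
transition network treats assignment flips at adjacent time points as
real transitions; it has no notion of assignment uncertainty beyond the
consensus likelihoods.
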