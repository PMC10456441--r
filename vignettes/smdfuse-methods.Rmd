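---
title: "Surrogate minimal depth forests for multimodal food authentication: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{smdfuse methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`smdfuse` implements an end-to-end analysis for two-class food
authentication from multimodal instrumental data: chemometric
preprocessing of LC-MS bucket tables, FT-NIR replicate spectra and
photometric spectra; class-weighted random-forest classification with
per-node surrogate splits; surrogate-minimal-depth (SMD) variable
selection; and mean-adjusted-agreement relation analysis of low-level
fused data.  This vignette describes the models, every tunable that
matters, and the decisions taken where the design was genuinely open.
It states no empirical number that the test suite does not itself
compute.

## The data model

All blocks share one container, the `feature_table`: a samples ×
variables matrix with class labels (`organic` / `conventional`) and
per-variable metadata (block tag and physical axis — m/z and retention
time for LC-MS buckets, wavenumber for NIR bins, wavelength for
photometry).  FT-NIR data enter as `replicate_spectra`: several
technical replicates per sample on one wavenumber grid, here 3720
points spanning 11,550–3950 cm⁻¹ stored descending.

## Preprocessing

**LC-MS** (`preprocess_lcms`): a bucket is kept when it is detectable
(value > 0; bucket tables encode absence as 0, and a flag switches to
non-missing semantics) in at least half of the samples of at least one
class — the group-presence rule with `min_fraction = 0.5`.  Rows are
then scaled to unit Euclidean norm (vector normalization, removing
global intensity differences between runs) and columns standardized to
mean 0, sd 1 with the *n* − 1 denominator (autoscaling); the scaling
parameters are stored for reuse on new data.  Autoscaling is applied
once to the full table, which is consistent with OOB-based evaluation
(no separate test partition exists that could leak).

**FT-NIR** (`preprocess_nir`), in this exact order: multiplicative
scatter correction (MSC) → first derivative → Savitzky–Golay smoothing
→ binning of five adjacent wavenumbers → pointwise median over the
technical replicates.  Decisions where the chain is underdetermined:

* *MSC reference*: the mean over all replicates of all samples in the
  processed set, stored in the result for reuse — the standard MSC
  convention.  Each spectrum `x` is regressed as `x ≈ a + b·ref` and
  returned as `(x − a)/b`; a slope below 1e−12 raises an error naming
  the replicate.  MSC is idempotent for a fixed reference.
* *Derivative*: central differences in the interior, one-sided at the
  ends, so the length is preserved and 3720 points still bin 5 → 744
  variables exactly.
* *Savitzky–Golay*: window 11, polynomial order 2 by default (both
  config-exposed; the common chemometric choice — the source chain
  states neither).  Each point is replaced by the centre value of the
  least-squares polynomial over its window.  The first and last
  half-windows are filled from polynomial fits over the first/last
  full window rather than by mirror padding: mirror padding breaks the
  filter's defining property of reproducing polynomials of degree ≤
  order exactly at the boundary, and the chosen scheme matches
  `signal::sgolayfilt` (an independent cross-check in the test suite).
* *Binning*: non-overlapping groups averaged; a shorter trailing group
  is averaged over its available points (irrelevant at 3720/5 but
  defined for general inputs); the binned axis value is the group's
  mean wavenumber.

**Photometry** (`preprocess_photometry`): vector normalization and
autoscaling only — dense absorbance spectra have no meaningful
presence filter.

## The surrogate random forest

`fit_forest` grows `ntree` unpruned binary classification trees in
compiled code.  For each tree, *n* samples are drawn with replacement
with probability proportional to the case weights; the samples never
drawn are the tree's out-of-bag (OOB) set (≈ 37 % under equal
weights — the suite checks the empirical OOB fraction against
1 − (1 − 1/n)ⁿ).  Defaults follow the field's conventions for this
analysis:

| parameter | default | meaning |
|---|---|---|
| `ntree` | 10,000 (full scale); 500–1000 at desk scale | trees |
| `mtry` | `floor(p^(3/4))` | candidates per node (267/142/91/350 at p = 1727/744/411/2471) |
| `min_node_size` | 1 | grow to purity |
| `s` | `ceiling(fraction·p)`, 5 % LC-MS / 20 % NIR | surrogates stored per node (87 and 149 at the study widths) |
| case weights | max class size / class size | weighted bootstrap |

Case weights act on the bootstrap *sampling* probabilities, matching
the cited implementation's semantics; node impurity is computed on
unweighted in-bag counts.  Splits are exhaustive over midpoints of
consecutive distinct values; ties in Gini decrease resolve to the lower
variable index, then the lower threshold, making fits bit-reproducible
under a seed (each tree seeds its own RNG stream from `(seed, tree)`,
independent of R's RNG state).

At every internal node the top `s` *surrogate splits* are stored.  For
each other variable the best mimicking split maximizes the agreement
`A` = fraction of in-node in-bag samples routed the same way as the
primary split, allowing direction reversal; the stored score is the
adjusted agreement `(A − m)/(1 − m)` with `m = max(p_L, p_R)`, so 1 is
a perfect mimic and anything not better than majority-guessing is ≤ 0
and discarded.  Surrogates use in-node in-bag samples only, consistent
with training-time information.  A degenerate primary split (`m = 1`)
stores nothing.

OOB evaluation (`oob_confusion`) votes per sample over the trees where
it was OOB; samples OOB in no tree (possible at very small `ntree`) are
excluded with a warning and counted in the report.  The printed layout
mirrors the conventional confusion table of this field: row-normalized
percentages per true class, per-class sensitivity on the diagonal,
per-predicted-class precision in a row labeled "Specificity", and the
overall accuracy in the corner.  One caveat the tests document: on
label-independent data the OOB vote is slightly *pessimistic* at small
*n* (each sample's OOB trees under-represent its own class in the
bootstrap), so the suite bounds only the optimistic direction when
checking chance-level behaviour.

## SMD selection and its threshold

A variable's surrogate minimal depth in a tree is the depth (root = 0)
of the shallowest node where it appears as primary splitter or stored
surrogate; variables absent from a tree contribute that tree's maximal
terminal depth — a bounded, data-driven penalty.  The mean over trees
is the SMD score; planted strong markers reach mean SMD near 0.02 in
the seeded test runs, and correlated variable groups are found jointly
— the property that distinguishes SMD from per-variable importances.

The selection threshold was the one genuinely open design problem, and
two natural constructions fail quietly; both are documented here
because the failure modes are instructive:

1. *Appending independently permuted shadow columns* and thresholding
   at a lower quantile of their SMD: vector normalization gives all
   real variables a common row factor (each sample's norm), so real
   variables weakly mimic each other while independent shadows cannot;
   real null variables sit systematically shallower than shadows and
   the type-I error inflates an order of magnitude above nominal.
2. *Appending a jointly permuted mirror* of the whole table preserves
   the shadows' internal dependence, but real and shadow groups then
   compete zero-sum for nodes within one forest: whichever group's
   common factor happens to correlate with the labels crowds the other
   out wholesale, and the selected fraction becomes bimodal across
   seeds.

`smd_threshold` therefore estimates the null directly: it refits the
forest `n_perm` times (default 3) on the *unchanged* table with
permuted class labels — preserving every between-variable dependence
while destroying exactly the label association — and pools the
per-variable scores.  Because tree shapes differ between a signal fit
(shallow trees) and a null fit (deep trees), raw depths are not
comparable across fits; scores are therefore taken on the *relative*
depth scale (per-tree depth divided by that tree's maximal terminal
depth; absent = 1, which keeps the absent-penalty rule), which is
shape-invariant.  The threshold is the 0.01 quantile of the pooled
null scores, and `select_variables` selects variables of the real fit
scoring strictly below it.  On an unstructured permuted-label null the
suite measures a selected fraction near the nominal 1 % (bounded at
5 % averaged over 20 seeds); on the default strong-signal data all
planted exclusive markers are recovered.  The `smd_result` reports
both the absolute mean SMD (the field's customary scale) and the
relative score used for selection.

## Relation analysis, fusion, clustering

For an ordered pair (i, j), `mean_adjusted_agreement` averages, over
all nodes where i is the primary splitter, the stored adjusted
agreement of j (0 when j is not among that node's stored surrogates);
variables that never split primarily yield zero rows and are counted.
The asymmetric matrix is symmetrized by averaging and the diagonal set
to 1.  The relation is computed among the SMD-selected variables by
default (a full-matrix mode exists for small p).

`low_level_fuse` concatenates preprocessed blocks column-wise after
verifying identical samples and disjoint variable ids; no rescaling is
applied beyond each block's own preprocessing (trees are invariant to
monotone per-variable scaling, and an optional post-merge autoscaling
flag exists).  The fused table of the study's widths, 1727 + 744 =
2471 variables, gives `default_mtry` = 350; the fused surrogate
fraction defaults to 5 % (which reproduces 124 at the full width).

`cluster_relation_matrix` applies Ward clustering (`ward.D2`, i.e.
Ward on Euclidean distances) to the rows of the symmetrized matrix and
cuts at `k = 3` by default, the number of labeled cluster types the
fused analysis distinguishes (pure LC-MS, pure NIR, mixed);
`cross_modal_report` labels each cluster single- or mixed-block and
lists members with their axes.  The dendrogram can be exported as
Newick (via `ape`).

## The synthetic-data generator

`generate_dataset` produces the structure this analysis assumes, with
ground truth for recovery tests.  Defaults are fixed once as the
package's study conditions:

* 20 organic / 40 conventional samples (the ≈ 1:2 imbalance of a
  typical authentication study, at a size where the whole pipeline
  runs in minutes), 300 LC-MS variables, 3720-point NIR grid with 5
  replicates, 411-point photometry.
* LC-MS background: log-normal(0, 1) intensities — strictly positive
  and right-skewed like MS intensities.
* 5 *exclusive* markers: exactly 0 in organic samples; present with
  probability 0.95 (log-normal intensity) in conventional samples —
  occasional zeros occur even in the carrying class, as a feed-additive
  carotenoid behaves.
* 10 *shift* markers: organic mean elevated by `effect_size` (1.5)
  background standard deviations, emulating lipids enriched by organic
  feed.
* A shared latent factor, standard normal with organic mean shifted by
  1.5: log-additively loaded on 10 LC-MS variables (keeping
  intensities positive) and added as a Gaussian absorption band at
  5750–5850 cm⁻¹ to the NIR spectra — the cross-modal lipid structure.
  An independent standard-normal factor drives a 5900–6100 cm⁻¹
  protein band that NIR alone sees.
* NIR replicate r of sample i is `a + b·(true spectrum) + noise` with
  `a ~ N(0, 0.05)`, `b ~ logN(0, 0.1)` — the scatter MSC removes.
* Photometry: two Gaussian bands, 480 nm stronger in conventional and
  450 nm stronger in organic samples, mimicking opposed carotenoid
  profiles.

What it deliberately does **not** emulate: chromatographic structure,
isotopes/adducts, ion mobility, realistic NIR band assignments beyond
the named regions, instrument drift, or between-farm nesting.  Passing
recovery tests on these data therefore demonstrates that the machinery
finds the encoded structure — not that real eggs are classifiable at
any particular accuracy; the study's printed accuracies require the
study's data.

## Problem sizes and numerical choices in the tests

The suite runs the full pipeline at 60 samples, 300 LC-MS variables,
the full 3720-point NIR grid and 200–500 trees — sizes chosen so every
statistical experiment (20-seed type-I control, 20-seed cross-modal
recovery, 1000-tree OOB calibration) completes in minutes on one core.
Oracle tests freeze expected values from independent implementations:
exhaustive split/surrogate search on ≤ 12-sample nodes, two-parameter
regression for MSC, solved least-squares systems for the
Savitzky–Golay weights (central weight 17/35 at window 5, order 2),
hand-enumerated depths on hand-built forests, and eigendecomposition
for PCA.  Master seeds derive per-stage child seeds through a fixed
Lehmer map (`child_seed`), so any stage reproduces in isolation.

## Known limitations

* With `min_node_size = 1` most nodes are tiny, and at tiny nodes many
  unrelated variables mimic any split perfectly by chance; these
  chance surrogates dilute the mean adjusted agreement of moderately
  correlated pairs (the relation averages over *all* nodes).  In the
  seeded cross-modal recovery experiment this asymmetrically weakens
  the LC-MS→NIR direction and the latent cluster is recovered in most
  but not all runs at the default 20 generator seeds; the mechanism,
  measured relation values and the experiment are recorded in the test
  suite.
* The OOB estimate is slightly pessimistic at small n (above).
* The SMD threshold costs `n_perm` additional forest fits.
* The forest is binary-class by design; multi-class would need a
  generalized Gini and per-class weights.
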