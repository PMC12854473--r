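---
title: "Tissue-architecture features and response modelling: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tissue-architecture features and response modelling: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histofeatr)
```

# What the package computes

`histofeatr` covers the analysis stages of a skin-histopathology pipeline
that sit *downstream* of deep-learning segmentation. Its inputs are the
artifacts such models emit: a per-nucleus table (centroid, contour polygon,
integer class among granulocyte, lymphocyte, plasma, stromal, tumor) and a
binary tumor-region mask at a known downsample factor, plus the physical
scale of the slide in microns per pixel (mpp). From these it

1. refines the cell classification (tumor calls outside tumor regions become
   non-neoplastic epithelial),
2. builds a three-zone partition of the slide — tumor interior, a 1 mm
   vicinity ring, and the remaining tissue,
3. computes a 317-feature whole-slide encoding, and
4. runs a cross-validated feature-selection and classification protocol to
   predict a binary clinical outcome (immunotherapy response) and rank the
   features driving it.

A synthetic-slide generator with exact ground truth makes every stage
testable without any real whole-slide image.

# The refinement rule

Nucleus-level classifiers cannot reliably separate tumor cells from healthy
epithelial cells: the two are morphologically close, and the distinction is
contextual. The tissue-level tumor segmentation provides that context, so
every nucleus carrying the tumor class whose centroid falls outside all
segmented tumor regions is relabeled as non-neoplastic epithelial (class 6).
Membership is decided at the centroid only — the same convention the
distance features use — with the mask pixel under a nucleus-frame point
$(x, y)$ given by $[\lfloor y/D\rfloor, \lfloor x/D\rfloor]$ at downsample
$D$ (x = column, y = row, origin top-left, 0-based). The rule is idempotent
and conserves the counts of all other classes, which the test suite asserts
on simulated slides.

Tumor regions are connected components of the mask under 8-connectivity
(diagonal contact joins; a configuration argument switches to 4). The
vicinity is the Euclidean dilation of the tumor union by
`round(width_mm * 1000 / (mpp * downsample))` mask pixels minus the tumor
itself, computed with a distance transform; the default width of 1 mm is the
scale at which peri-tumoral immune infiltrate is conventionally assessed.
Zones are therefore disjoint: tumor interior, ring, outside.

# The expanding-rectangle closest-cell distance

For a source class A and target class B, the slide-level feature is the mean,
over source cells inside tumor regions, of the distance to the nearest
same-region target cell. The nearest cell is found with a growing rectangular
search area: at step $\lambda = 1, 2, \dots$ the rectangle centered on the
source has full side lengths $f\lambda l_t \times f\lambda w_t$, where
$l_t, w_t$ are the bounding-box dimensions of the source's tumor region and
$f = 0.05$; at the first $\lambda$ capturing at least one target (closed
inequalities — a boundary hit counts), the minimum Euclidean distance over
the captured set is returned. Rectangles are used instead of disks because
candidate membership reduces to two absolute-value comparisons.

Three consequences matter:

* **Overestimation.** The capture set is rectangle-shaped, so a corner cell
  can be captured while a nearer cell just outside the rectangle is not;
  the result is then a real inter-cell distance that exceeds the true
  nearest-neighbour distance (never an underestimate — a property test
  enforces the bound against a brute-force oracle).
  `mc_overestimation_probability()` quantifies the effect for the canonical
  geometry: a square of side $2r_1$ whose circumscribed circle (radius
  $r_1\sqrt 2$) holds $N$ uniform cells. The event requires a cell inside
  the square while the globally nearest lies outside; with a single cell the
  probability is exactly zero, and it falls steeply with $N$ (about
  $1.9\times10^{-2}$ at $N=2$ and $3\times10^{-4}$ at $N=10$, recomputed by
  `scripts/acceptance.R`). The main text's alternative reading of the
  sampling disk (radius $2r_1$) is exposed as `geometry = "radius_2r1"`;
  inscription is the self-consistent default.
* **Confinement.** The search never leaves the source's tumor region:
  targets are restricted to cells with the same region id. Sources in
  regions with no target cell are skipped and counted, as are searches that
  hit the `lambda_max` cap (default: the smallest step spanning the whole
  bounding box from any interior point, plus one, i.e.
  $\lceil 2/f\rceil + 1$), which guards termination.
* **Equivalence of implementations.** `expanding_min_distance()` steps
  through $\lambda$ literally; the production path computes each target's
  capture step in closed form,
  $\lambda_{ij} = \max(\lceil 2|dx|/(f l_t)\rceil,
  \lceil 2|dy|/(f w_t)\rceil, 1)$, and takes the minimum-distance target
  among those at $\min_j \lambda_{ij}$. The suite asserts the two agree
  exactly, including same-class self-exclusion.

Distances are reported in pixels and microns ($\times$ mpp); when source and
target class coincide the source is excluded from its own target set.

# The smoothed log ratio

Count ratios between cell classes are heavy-tailed, so the encoding uses
$$\eta(n_A, n_B) = \frac{\ln n_A + \epsilon}{\ln n_B + \epsilon},
\qquad \epsilon = 10^{-3},$$
undefined (missing) when either count is zero. $\eta(n, n) = 1$ exactly, and
reciprocity holds to within $\epsilon$ for counts $\ge 2$. The log is
natural by default (switchable); $\epsilon$ sits outside the logarithm.

# The feature registry

The encoding is a fixed, ordered catalogue of 317 named features built
programmatically in one versioned function (`feature_registry()`), so an
alternative catalogue can replace it verbatim. Five families over the zones
whole / tumor / vicinity / outside:

| family | structure subset | non-structure complement |
|---|---|---|
| fraction | 6 classes x 4 zones (24) | composite immune fraction x 4 |
| density (per mm^2) | 6 x 4 (24) | immune composite x 4, overall cellularity |
| repartition | 6 classes x 3 zones (18) | — |
| ratio | 25 canonical log ratios (tumor + vicinity) | 95 remaining log ratios, 90 raw count ratios |
| distance | 16 ordered pairs, microns | the same 16 in pixels |

Exactly 107 entries carry the structure flag and form the default analysis
subset: size- and unit-independent descriptors of tissue architecture. The
log-ratio structure set covers unordered class pairs in the tumor and
vicinity zones, excluding epithelial pairs inside the tumor because the
refinement makes epithelial cells there impossible by construction
(10 + 15 = 25). Distance features exist only for granulocyte, lymphocyte,
plasma and tumor cells inside tumor regions. No nucleus-morphology features
(area, circularity) exist anywhere in the catalogue. Undefined values (an
empty zone, a zero count inside a logarithm, a distance without eligible
sources) are `NA` internally and `null` in the flat feature JSON; tumor-zone
repartitions on a tumor-free slide are a true 0, not missing.

# The response-prediction protocol

The cohort protocol mirrors a small-cohort clinical setting (45 samples,
28 responders / 17 non-responders):

* **Cross-validation.** Stratified 3-fold (train 2/3, test 1/3), so both
  labels appear in every test fold at these group sizes; the fold shuffle is
  the only seeded randomness.
* **Imputation.** Missing feature values are filled with training-fold
  medians; test folds reuse the training medians, never their own.
* **Selection.** Greedy mRMR on the training split only, FCQ-style:
  relevance is the two-group ANOVA F statistic, redundancy the mean absolute
  Pearson correlation with the already-selected set, and the criterion their
  quotient (the additive form collapses to pure relevance ranking when F
  statistics are large, and cannot reject an exact duplicate of the first
  pick). The mean redundancy is floored at $10^{-3}$ so near-orthogonal
  candidates cannot gain unbounded leverage; constant features get zero
  relevance rather than an error; ties resolve to the earlier column.
* **Classifier.** Gradient-boosted trees (xgboost) with the library's
  default hyperparameters and 100 rounds, single-threaded for bit
  reproducibility — no tuning, as nested search is not affordable at this
  cohort size.
* **Operating point.** `sweep_n_features()` scores balanced accuracy on the
  test folds for every subset size $N \in [1, 107]$ and takes the best mean
  (smallest $N$ on ties). On 45 samples the argmax over 3 folds of 15 test
  samples is itself noisy, so `response_protocol()` accepts a fixed
  `n_best` (19, a published operating point for this design) for
  experiments that need a stable one.
* **Feature scoring.** Per split the selected set is an ordered list; a
  feature ranked $r$ (1-based) contributes a pre-score $10^{N_{best}-r}$,
  pre-scores are summed over splits, and the final score is
  $s = \log_{10}\sum_l 10^{N_{best}-r_l}$, alongside the occurrence count
  $c$ (number of splits selecting the feature). Base 10 makes pre-scores
  decade-separated by rank, so ties in $c$ resolve in favour of better
  ranks; a feature ranked first in all three splits of 19 scores
  $\log_{10}(3\cdot10^{18}) \approx 18.477$.
* **Evaluation.** Per-fold ROC curves on test-fold scores, vertically
  averaged on a common false-positive-rate grid; mean AUROC plus or minus
  its across-fold standard deviation.

# The synthetic-data generator

`simulate_slide()` emulates only what the upstream models would emit:
tumor blobs (unions of jittered disks) rasterized into the mask, and nuclei
placed by independent Poisson sampling — per class and zone the count is
Poisson with mean intensity x zone area (intensities in cells per mm^2) and
positions are uniform over the zone's pixels. Defaults describe a
3.6 x 3.6 mm field at 0.5 um/px (mask downsample 16) with one ~0.5 mm-radius
blob and intensities loosely typical of an H&E skin-cancer section (tumor
regions dominated by tumor cells at 500/mm^2 with moderate immune
infiltrate; a stroma-rich vicinity; sparse epithelium outside). Everything
the generator draws is recorded as exact ground truth, and a suite invariant
recomputes the per-zone counts from the emitted artifacts.

Two cohort modes plant group effects:

* **Slide level** (`simulate_cohort()`): effects are class- and
  zone-specific intensities; per sample the group mean is jittered by a
  truncated multiplicative-normal factor (sd 0.15; 0.30 for the stromal
  compartment, whose content varies most between sections) before Poisson
  sampling. This exercises the whole pipeline, but any intensity effect
  propagates into every derived readout of its channel — fractions,
  repartitions, ratios, aggregates — so no slide-level cohort can have
  "exactly k" informative features.
* **Feature level** (`simulate_feature_cohort()`): the structure-feature
  table is drawn directly, with exactly the planted features carrying
  group-conditional Gaussians and every other feature label-independent.
  This is the sharp setting for testing selection and scoring: the default
  four effects (lymphocyte fractions in and around the tumor, the
  granulocyte-lymphocyte vicinity log ratio, the granulocyte-plasma
  distance) separate the groups at roughly two within-group standard
  deviations each, a regime calibrated once so that the protocol recovers
  all four among its top eight and classifies at AUROC >= 0.9 in the large
  majority of seeds.

What the simulations do **not** model: spatial clustering of immune cells
(placement is uniform within zones), correlated feature noise, staining or
scanner variation, segmentation errors, multi-center batch structure, or
nucleus morphology. Passing tests therefore demonstrate the correctness of
the computations under the stated point-process model, not clinical
performance on real slides.

# Numerical choices and degenerate inputs

* Rectangle membership uses closed inequalities; ties in the minimum
  distance need no tie-break (the value is equal either way).
* The rectangle has *full* side lengths $f\lambda l_t \times f\lambda w_t$
  (half-extent $f\lambda l_t/2$); the alternative half-extent reading is a
  one-line change in `search_config()`.
* Empty zones yield missing fractions/densities; a class absent from the
  slide yields missing repartitions; zero counts yield missing ratios.
* `cv_folds()` refuses folds that lose a label; `mrmr_select()` refuses
  unimputed input and `n` beyond the table width.
* Problem sizes in the test suite are chosen for single-CPU runs: the
  distance-oracle sweep uses 1000 compact single-blob slides
  (~100 cells/region), the recovery experiment 20 seeded 45-sample
  feature-level cohorts, the Monte-Carlo bands 2 x 10^6 draws.

# Known limitations

* The 317-entry catalogue is this package's own documented enumeration over
  the five families; other implementations of the same encoding may name or
  order features differently, which is why the registry is versioned.
* The expanding search is exact only up to the documented overestimation
  mode; slides with very sparse target classes inside small regions are the
  worst case.
* mRMR is the FCQ variant for continuous features and a binary label; other
  relevance/redundancy estimators (mutual information) are out of scope.
* The mean ROC uses vertical averaging; threshold-level averaging would
  differ slightly at these test-fold sizes.
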