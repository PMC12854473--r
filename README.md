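# histofeatr

Tissue-architecture feature extraction and response modelling for skin
histopathology, in R.

Deep-learning models for whole-slide images (WSIs) of cutaneous squamous
cell carcinoma emit two artifacts: a per-nucleus segmentation with class
calls (granulocyte, lymphocyte, plasma, stromal, tumor) and a binary
tumor-region mask. `histofeatr` implements everything downstream of those
models, for computational-pathology researchers who want an interpretable,
fixed-length encoding of a slide and a small-cohort prediction protocol on
top of it:

* **Refinement** — tumor-called nuclei outside the segmented tumor regions
  are relabeled as non-neoplastic epithelial, the distinction a
  nucleus-level classifier cannot make alone.
* **Zones** — connected tumor regions (8-connectivity), a 1 mm vicinity
  ring built by Euclidean dilation, and the remaining tissue.
* **317-feature encoding** — per-zone class fractions and densities, zone
  repartitions, smoothed log count ratios
  η = (ln n_A + ε)/(ln n_B + ε) with ε = 10⁻³, and average closest-cell
  distances between classes inside tumor regions, computed with an
  expanding rectangular search: a rectangle of side lengths
  f·λ·l_t × f·λ·w_t (f = 0.05; l_t, w_t the tumor bounding box) grows in
  integer steps λ until it captures a target cell, and the minimum
  Euclidean distance over the captured set is taken. A 107-feature
  structure subset forms the default analysis set.
* **Response modelling** — stratified 3-fold cross-validation with mRMR
  feature selection on the training splits, gradient-boosted trees with
  default hyperparameters, a balanced-accuracy sweep over the number of
  kept features N ∈ [1, 107], and per-feature occurrence/rank scores
  c and s = log₁₀ Σ 10^(N_best − rank) aggregated across folds.
* **Synthetic data** — slide and cohort generators with exact ground truth
  (Poisson placement with class- and zone-specific intensities; planted
  group effects), plus a Monte-Carlo analysis of the rectangle-search
  distance overestimation.

The methods vignette (`vignettes/tissue-features.Rmd`) documents the model,
parameter choices and limitations in detail.

## Worked example

```r
library(histofeatr)

# a synthetic slide standing in for segmentation-model output
s <- simulate_slide(slide_sim_config(seed = 42), sample_id = "demo")
s$annotation
#> <slide_annotation> demo: 6848 nuclei, 7200 x 7200 px, 0.500 um/px
#>   granulocyte=659, lymphocyte=1134, plasma=648, stromal=3274, tumor=1133

regions <- label_tumor_regions(s$mask, mpp = s$annotation$mpp)
ann <- s$annotation |>
  assign_nuclei_to_regions(regions) |>
  reclassify_epithelial()
attr(ann, "n_reclassified")
#> [1] 670     # tumor calls outside tumor regions, now epithelial

fv <- compute_features(ann, regions)   # tibble: 317 rows (feature, value)
dplyr::filter(fv, feature %in% c("fraction_lymphocyte_tumor",
                                 "dist_granulocyte_plasma_um"))
#> 1 fraction_lymphocyte_tumor   0.120   # share of tumor-zone cells
#> 2 dist_granulocyte_plasma_um 68.9     # mean closest-cell distance, microns
```

12% of the cells inside tumor regions are lymphocytes, and a granulocyte's
nearest plasma cell in the same tumor region is 69 µm away on average —
the kinds of quantities the cohort model then ranks.

```r
# a 45-sample cohort (28 responders / 17 non-responders) with four
# planted feature effects, and the full selection/scoring protocol
ft <- simulate_feature_cohort(seed = 1)
prot <- response_protocol(ft, ft$label, seed = 1, n_best = 19)
prot
#> <hf_sweep> 3 folds, N in [1, 107]; n_best = 10 (mean balanced accuracy 0.963)
#> <hf_response_fit> 3 folds, 19 features/fold: mean AUROC 0.994 +/- 0.011
#> top features by (c, s):
#>   feature                                       c     s
#> 1 fraction_lymphocyte_tumor                     3  18.0
#> 2 ratio_log_granulocyte_lymphocyte_vicinity     3  18.0
#> 3 dist_granulocyte_plasma_um                    3  18.0
#> 4 fraction_lymphocyte_vicinity                  3  16.1
```

All four planted features (the rows shown) head the aggregated ranking:
each was selected in all 3 folds (c = 3) at early ranks (s near
N_best − 1 = 18), and the classifier separates the groups almost perfectly.
`autoplot()` methods draw the sweep curve and the per-fold/mean ROC;
`tidy()`/`glance()` return the underlying tables.

A command-line front end in `inst/scripts/histofeatr` exposes the same
steps (`refine`, `features`, `select`, `classify`, `simulate`,
`mc-overestimate`) for shell pipelines.

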