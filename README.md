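# histopcr

Quantitative digital histopathology (pathomics) for predicting
**pathological complete response (pCR)** to neoadjuvant chemotherapy in
breast cancer from **pre-treatment core-biopsy slides**. pCR — no
residual invasive or nodal disease at surgery — strongly predicts
survival, but standard pathologic assessment only reveals it after
months of chemotherapy. This package is for computational-pathology
researchers who want a complete, testable implementation of the
tile → segment → featurize → aggregate → classify pipeline, and for
methodologists who need a synthetic-cohort harness in which every stage
of such a pipeline can be validated without access to patient data.

## What it implements

* **Tumor-region tiling** — non-overlapping 768 × 768 tiles on a fixed
  grid; a tile is kept iff tumor fraction > 0.5 and white-background
  fraction < 0.1 (both strict).
* **Nuclei-mask reconstruction** — 256 × 256 patches with 128-px
  overlap, per-pixel averaging of patch probability maps, threshold
  0.5 (strict), removal of 8-connected components under 50 px. The
  probability-producing segmenter is a pluggable contract; a
  deterministic classical baseline (Otsu + distance transform) ships
  with the package.
* **A 549-feature pathomic registry** in five families:
  nuclear morphology + Fourier shape descriptors (16), nuclear
  intensity/gradient (20), IBSI-style texture — first-order, GLCM,
  GLRLM, GLSZM, GLDM, NGTDM — (93), nuclear-architecture graphs —
  Voronoi, Delaunay, MST, k-NN with disorder
  $1 - 1/(1+\sigma/\mu)$ — (49), and the texture block on the four
  orthonormal Haar sub-bands (371).
* **Patient aggregation** — nuclei-count-weighted means over tiles,
  $\bar{x}_f = \sum_t w_t x_{tf} / \sum_t w_t$, sentinels excluded.
* **Response modelling** — min–max normalization fitted on training
  rows, gradient-boosting importance-gain feature selection, SMOTE
  doubling of the minority (pCR) class, a GBM with learning rate 0.1,
  depth 10, 2000 estimators, stratified 5-fold cross-validation, and
  held-out evaluation (accuracy, sensitivity, specificity, trapezoidal
  AUC) at the 0.5 cut-off — across seven feature-subset experiments.
* **A synthetic cohort generator** — tiles with elliptical nuclei on a
  jittered triangular lattice plus ground-truth masks, and a clinical
  table following the published cohort's per-class covariate marginals
  (149 patients, 34% pCR); placement jitter and intra-nucleus noise are
  configurable class effects, so the pipeline's ability to recover a
  known signal is machine-checkable.

## Worked example

Simulate a small cohort with a planted nuclear-architecture effect,
reconstruct nuclei masks, extract features, and run the graph-family
experiment:

```r
library(histopcr)

spec <- cohort_spec(n_patients = 48, pcr_fraction = 1 / 3,
                    tiles_per_patient = 1, tile_size = 384,
                    nuclei_per_tile_range = c(30, 40),
                    disorder_effect = 6, texture_effect = 18, seed = 7)
cohort <- generate_cohort(spec)
table(cohort$clinical$label)
#> non-pCR     pCR
#>      32      16

# one tile through segmentation and the full registry
tile <- cohort$tiles$P001[[1]]
lm <- segment_tile(tile$image, patch_size = 256, stride = 128)
lm
#> nuclei label map: 31 nuclei on a 384 x 384 grid
fv <- extract_tile_features(tile$image, lm)
round(fv[c("Morphology_Area_Mean", "Intensity_Stddev",
           "GLDM_DependenceEntropy", "Delaunay_Sides_Stddev",
           "Voronoi_Max_Distance_Disorder",
           "Wavelet_HL_GLDM_DependenceEntropy")], 3)
#>              Morphology_Area_Mean                  Intensity_Stddev
#>                           133.935                            53.815
#>            GLDM_DependenceEntropy             Delaunay_Sides_Stddev
#>                             5.381                            19.708
#>     Voronoi_Max_Distance_Disorder Wavelet_HL_GLDM_DependenceEntropy
#>                             0.089                             5.306

# full protocol on the graph family
split <- split_cohort(cohort, 0.75, seed = 1)
tab <- cohort_patient_table(cohort, split)
rep <- run_experiment(tab, "graph", seed = 1, folds = 5)
rep$selection$selected
#> [1] "NN_Distance_K1_Stddev"
```

which prints, for this 48-patient demo (36 train / 12 test):

```
CV AUC 0.57 +/- 0.15 | test acc 0.83, sens 0.75, spec 0.88, AUC 0.81
```

The selected feature is the spread of nearest-neighbour spacing —
exactly the measurement the planted jitter effect perturbs. At demo
size the per-fold CV estimate is coarse and the 12-patient test set
granular; the acceptance script below runs the calibrated study
conditions, where the held-out AUC is far higher.

A command-line front end wraps the same functions
(`inst/cli/histopcr.R`): `simulate`, `tile`, `segment`, `extract`,
`train`, `evaluate`, `run-all`.

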