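# habitatmri

Data-driven mapping of tumor oxygenation and perfusion heterogeneity from
combined **DCE-MRI** (dynamic contrast-enhanced) and **OE-MRI**
(oxygen-enhanced) acquisitions.

Tumors contain functionally distinct sub-regions — necrotic, hypoxic,
well-perfused — and hypoxia in particular drives therapy resistance. DCE-MRI
tracks the R1 = 1/T1 increase after a gadolinium bolus (perfusion /
permeability); OE-MRI tracks the R1 increase after switching the breathing
gas to 100% oxygen (oxygen delivery). Tissue that enhances with gadolinium
but is refractory to oxygen is a candidate hypoxic compartment. Instead of
binarizing each modality against a priori thresholds into three classes,
`habitatmri` clusters voxel-wise enhancement features with Gaussian mixture
models and lets three evaluation metrics decide which feature set and how
many tissue "habitats" the data robustly support.

The package is aimed at quantitative MRI researchers working with dynamic
preclinical (or clinical) tumor data who want an objective, reproducible
habitat segmentation with built-in model selection.

## What it computes

For voxel signals $S$ under the spoiled gradient echo model
$S = S_0 \sin\alpha\,(1-E_1)/(1-E_1\cos\alpha)$, $E_1 = e^{-TR/T_1}$:

1. **Relaxometry** — variable flip angle T10/S0 mapping (DESPOT1-seeded
   nonlinear least squares), OE baseline-drift correction via an
   exponentially time-varying effective flip angle
   $\alpha(t) = \alpha_0(1 + A(1-e^{-t/\tau}))$, and frame-wise inversion of
   the signal equation to $\Delta R_1(t) = R_1(t) - 1/T_{10}$.
2. **Preprocessing** — removal of the top 1% modulus-AUC voxels per
   modality (erratic enhancement at edges/vessels).
3. **Features** — a 2-D signed AUC set (first 90 s post-Gd of DCE; all
   post-switch OE frames) and a 4-D PCA set over scaled, concatenated
   DCE+OE curves.
4. **Clustering** — full-covariance Gaussian mixtures, 10 random restarts,
   best log-likelihood kept, clusters relabeled by ascending mean DCE AUC,
   3D region maps and mean within-cluster curves.
5. **Model selection** — AIC ($2k - 2\ln L$), spatial contiguity z-scores
   (26-connected component counts against a label-resampling null), and
   bootstrap cluster-stability silhouettes (Hungarian-matched refit
   centers). `select_optimum` picks the largest cluster number that is
   simultaneously stable (median silhouette ≥ 0.8) and spatially coherent
   (median z ≥ 3).
6. **Comparison** — the prior threshold-based three-class method (Welch
   enhancement calls), Cohen's κ, proportional agreement φ, and
   Bland–Altman statistics on per-class voxel counts.

A digital phantom module generates synthetic DCE/OE/VFA data with known
ground-truth habitats on the same acquisition geometry and timing as the
targeted protocols (OE: 42 × 28.80 s frames, switch at frame 19; DCE:
96 × 5.78 s frames, injection at frame 25), so the whole pipeline is
testable end to end without any external data.

## Worked example

```r
library(habitatmri)

res <- run_habitat_pipeline(habitat_pipeline_config(seed = 7))
print(res)
#> <habitat_pipeline_result> 4 tumors, selected pca / N_C = 3
#>   vs TBM (pooled): phi = 0.832, kappa = 0.709

res$report
#>   feature_set nc      aic   z_median stability_median
#> 1         auc  2 60967.61 -5.1695393        0.9854571
#> 2         auc  3 60182.11  3.4977027        0.9089031
#> 3         auc  4 60166.42  3.4638713        0.6847802
#> 4         auc  5 60133.40  5.2417464        0.6373579
#> 5         pca  2 24613.51  0.1749816        0.9867723
#> 6         pca  3 23664.81  3.9677829        0.9684001
#> 7         pca  4 23550.46  2.8794888        0.9013388
#> 8         pca  5 23504.76  4.7494932        0.7410862
```

Reading the report: stability silhouettes are near +1 up to three clusters
(0.91–0.99) and degrade beyond for the AUC set (≈ 0.64–0.68), while for
the PCA set the four-cluster solution that remains fairly stable fails the
spatial-contiguity gate (median z ≈ 2.9 < 3); three-cluster maps are far
more contiguous than the label-shuffling null (median z ≈ 3.5–4.0). The
rule therefore selects the PCA feature set with N_C = 3 — the phantom's
generative habitat count — and the resulting habitat map agrees with the
threshold-based three-class map at κ ≈ 0.71, φ ≈ 0.83 (pooled over
≈ 3200 voxels). Per-tumor maps are in `res$tumors[[i]]$habitat_map`, mean
within-cluster enhancement curves in `res$cluster_curves`.

A thin CLI wrapper is installed with the package
(`system.file("cli/habitatmri.R", package = "habitatmri")`) with
`phantom` and `run` subcommands for shell use; pipeline configurations can
also be given as YAML (`load_pipeline_config`).

## Method details

See the methods vignette (`vignettes/habitat-mapping-methods.Rmd`) for the
signal model, the drift-correction parameterization, the evaluation
metrics, the phantom's design (including why within-habitat biological
variability is essential for a meaningful stability analysis), numerical
conventions, and limitations.
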