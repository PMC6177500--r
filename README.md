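# wallmap

Three-dimensional analysis of the arterial vessel wall at the carotid
bifurcation, for researchers relating local hemodynamics to wall
remodelling: per-vertex maps of wall thickness (WT), wall shear stress
(WSS) and lumen diameter (D) on triangulated surfaces, cohort-averaged
atlas maps, bootstrap correlation inference that respects spatial
autocorrelation, and regression-based prediction of individual 3D WT maps.

## The model

All maps live on the vertices of a lumen surface mesh. Per vertex:

* `WT` (mm) — shortest distance from the lumen surface to the outer
  (adventitial) wall surface, point-to-triangle;
* `D` (mm) — twice the distance to the vessel centerline (maximal
  inscribed-sphere radius, traced by cross-section centroid chaining);
* `WSS` (Pa) — `μ · |∂v/∂n|` at the wall, the velocity gradient estimated
  by a quadratic (smoothing-spline) fit through velocity samples at three
  equidistant points along the inward normal, spanning one radius.

The core statistical object is the vertex-wise linear model

```
WT = β0 + β1·WSS + β2·D + β3·WSS·D + ε
```

fitted per subject (`fit_wt_regression()`, a classed model object with
`coef`/`predict`/`residuals`/`summary`/`simulate` methods) and on
bootstrap-resampled cohort-averaged maps (`fit_bootstrap_regressions()`):
subjects are drawn with replacement, maps are averaged vertex-wise on a
shared geometry (`build_shared_geometry()`, rigid alignment + barycentric
correspondence), the model is refitted per replicate, and the ensemble mean
coefficients predict individual WT maps from individual WSS and D maps
(`predict_wt_map()`). Correlations between averaged maps use Spearman's ρ
with percentile 95% CIs over the bootstrap replicates
(`bootstrap_correlations()`); per-subject correlations are summarised with
a Fisher z-test (`fisher_z_test()`).

Because cohort MRI data of this kind are not publicly deposited, the
package includes a synthetic bifurcation generator (`generate_cohort()`)
with analytic ground truth — parametric CCA→ICA+ECA geometry with a carotid
bulb, near-parabolic velocity volumes, and WT fields built from the model
above — against which every estimator is validated.

## Worked example

```r
library(wallmap)

config  <- cohort_config(n_subjects = 6, seed = 42)   # study defaults
subject <- generate_cohort(config, velocity = TRUE)[[1]]

wt  <- compute_wall_thickness(subject$lumen, subject$outer_wall)
cl  <- compute_centerline(subject$lumen)
d   <- compute_diameter_map(subject$lumen, cl)
img <- correct_background_offset(subject$velocity,
                                 static_tissue_mask(subject$velocity, subject$lumen))
wss <- compute_wss_map(subject$lumen, img, d)

print(wss)
#> scalar_map [wss, Pa]: 1370 vertices, 0 missing
#>   range 0.03048 .. 2.54, mean 1.358

fit <- fit_wt_regression(wt, wss, d, source = subject$subject_id)
print(fit)
#> wt_fit (wss + d + wss_d) [S01]
#> (Intercept)         wss           d       wss_d
#>      0.8322     -0.1527      0.1303     -0.0066
#> R-squared 0.826 on 1370 vertices

evaluate_prediction(wt, predict(fit))
#> prediction_eval: rho 0.916 | Bland-Altman mean diff -0.000 mm, LOA 0.186 mm | max WT 1.60 -> 1.57 mm (n=1370)

spearman_rho(wt, wss)
#> [1] -0.7390504
```

The WSS map spans ~0.03–2.5 Pa (low at the bulb, high in the narrow ECA);
thickness anti-correlates with shear (ρ = −0.74 for this subject), and the
full interaction model explains 83% of the WT variance on the measured
maps. `run_pipeline()` chains all of the above for a whole cohort —
simulation, per-subject maps, atlas, individual and bootstrap statistics,
prediction and evaluation — and writes CSV tables plus a JSON summary;
`inst/scripts/wallmap-run.R` is a command-line wrapper around it.

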