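---
title: "Wall maps on the carotid bifurcation: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wall maps on the carotid bifurcation: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Atherosclerotic wall thickening at the carotid bifurcation co-localises
with regions of low wall shear stress (WSS), and the wall is also
dimensioned with vessel calibre (law of Laplace). `wallmap` implements a
three-dimensional framework that relates, vertex by vertex on a surface
mesh of the bifurcation, three quantities:

* **WT** — wall thickness (mm): shortest distance from a lumen-surface
  vertex to the outer (adventitial) wall surface;
* **WSS** — wall shear stress magnitude (Pa): dynamic viscosity times the
  wall-normal velocity gradient estimated from a three-component,
  time-averaged velocity volume;
* **D** — local lumen diameter (mm): twice the distance from a surface
  vertex to the vessel centerline.

The central model is the vertex-wise linear regression with interaction

$$
WT = \beta_0 + \beta_1\,WSS + \beta_2\,D + \beta_3\,WSS \cdot D + \varepsilon ,
$$

fitted both per subject (individual model) and on bootstrap-resampled
cohort-averaged maps: subjects are drawn with replacement, each map is
averaged vertex-wise on a shared geometry, the model is refitted on every
averaged triple, and the ensemble mean coefficients are used to predict
individual 3D WT maps from individual WSS and D maps.  Spatial
autocorrelation of surface maps invalidates naive vertex-level tests;
resampling whole subjects is the inferential answer, for correlations
(Spearman's $\rho$ between averaged maps, percentile 95% CI over B = 1000
replicates) as for regression coefficients.

Because no subject-level data of this kind are publicly deposited, the
package ships a synthetic cohort generator with exact ground truth, and
every estimator is validated against analytic oracles on that synthetic
data.

# Estimators

## Wall thickness

Point-to-*surface* (not point-to-vertex) distance: for each lumen vertex,
the exact closest point over candidate outer-wall triangles (screened by
the 32 nearest face centroids).  This keeps the estimate independent of the
outer mesh resolution.  An outer wall that touches or crosses the lumen
(nearest point on the inward side of the vertex normal) is rejected with
the offending vertex indices.  On concentric cylinders of radii 3 and 4 mm
the map equals 1 mm up to chordal faceting, which can only *shrink* the
distance (by $\approx r\,\pi^2/2n^2$ for an $n$-gon ring).

## Centerline and diameter

The centerline is traced by cross-section centroid chaining: starting from
the centroid of an open boundary cap, a slab of vertices perpendicular to
the running direction is collected every 1.5 mean edge lengths; its
in-plane centroid is the next centerline point and the mean in-plane vertex
distance is the local inscribed radius.  One refinement pass per step
(re-slicing around the new centroid) and direction damping (average of the
previous and the new direction) stabilise curved tubes, where a naive slab
alternately straddles one or two mesh rings.  For a bifurcation, the CCA is
traced inlet-to-apex and each daughter branch outlet-to-apex, so the two
returned paths share the CCA segment.  Caps are recognised as *clean*
boundary components (every vertex on exactly two boundary edges) farthest
from the apex within each branch — ragged junction seams are thereby never
mistaken for inlets.  Validation: on a straight cylinder the traced axis is
exact to machine precision; on a torus segment (bend radius 20 mm, tube
radius 3 mm) the inscribed radius stays within ±5%.

The diameter map is $D = 2\times$ the distance to the nearest centerline
point (distance to the polyline's segments, minimum over branches; at the
apex the nearest branch wins, ties broken by branch order).

## Wall shear stress

For each vertex, velocity vectors are interpolated trilinearly at three
equidistant points along the inward normal — at the wall, at half the local
radius and at the local radius ($r = D/2$) — and rotated into a local wall
frame: the primary in-plane axis is the tangential projection of the
velocity at the innermost sample, the secondary its cross product with the
normal.  Per in-plane component a quadratic smoothing spline is fitted to
velocity versus distance (with three points and zero smoothing this is the
unique interpolating quadratic; the `smoothing` parameter adds a ridge
penalty on curvature, shrinking towards the least-squares line) and its
derivative is evaluated *at the wall*.  With velocities in cm/s and
distances in mm, 1 (cm/s)/mm = 10 s⁻¹; WSS = $\mu\,|\nabla v|$ in Pa.
Samples falling outside the image mark the vertex missing, and missingness
propagates through every downstream statistic.

Blood viscosity defaults to $\mu = 3.2\times10^{-3}$ Pa·s (a standard
literature value); it is configurable and recorded on every WSS map.

Validation against the Poiseuille closed form $\tau = 2\mu v_{peak}/R$ uses
8 voxels per radius, where the median error is 5–8% for
$R \in \{2,3,4\}$ mm.  The dominant error is wall partial volume: the
interpolated wall sample mixes intraluminal velocities with extraluminal
zeros, biasing the gradient low by $\approx 0.55\,(\text{voxel}/R)$ — at
0.5 mm voxels and $R = 2$ mm this is ~14%, the well-known underestimation
of velocity-encoded WSS at clinical resolution.

## Background phase offset

`correct_background_offset()` subtracts the mean velocity over a
static-tissue voxel mask from every component, mirroring the standard
phase-contrast correction; `static_tissue_mask()` builds such a mask from
voxels at least 5 mm from the lumen surface.  An offset applied and then
corrected changes the WSS map by well under 2%.

## Shared geometry and averaging

The atlas is the first subject's mesh.  Every subject is rigidly aligned to
it — apex translation, rotation aligning the CCA and ICA branch directions,
then trimmed iterative-closest-point refinement (Kabsch updates on the best
80% of pairs) — and each atlas vertex takes the barycentric interpolation of
the subject's map at the closest surface point, gated at twice the atlas
mean edge length.  Barycentric (rather than nearest-vertex) correspondence
matters quantitatively: weight-1 correspondence adds mesh-resolution noise
to the *regressors* of the cohort-averaged fit, which attenuates
coefficients.  Cohort statistics use the *complete-vertex* set (atlas
vertices covered by every subject for every quantity) and averaging over a
subject multiset is the plain arithmetic mean with available-case handling
and per-vertex counts.

## Prediction and agreement

Predictions are raw linear-model output — negative values are retained and
counted (clipping at zero is available for display only).  Agreement
between an original and a predicted WT map is summarised by Spearman's
$\rho$ over all vertices, the Bland–Altman mean difference and limits of
agreement ($1.96\times$ SD of paired differences), and the "maximum WT" of
each map defined as the mean of its top 5% of values (set size
$\lceil 0.05\,n\rceil$, ties broken by value then vertex index).
Self-fit evaluation uses the subject's native mesh vertices;
cohort-coefficient prediction is evaluated on native maps as well.

# The synthetic cohort generator

The generator defines the study conditions; its defaults are fixed and are
what all shipped validation runs use.

**Geometry.**  Each subject is a clipped union of three straight tubes: a
CCA (radius 3 mm, length 20 mm) splitting at the origin into an ICA
(2.2 mm, 15 mm) and an ECA (1.8 mm, 15 mm) at ±25° in the x–z plane.  The
daughter ostia flare smoothly up to ~1.1× the CCA end radius, which both
closes the junction into a watertight-enough surface (seam gaps of at most
about one edge length) and mimics the carotid bulb.  Cross-section rings
have 24 vertices at 0.8 mm spacing; inward normals are analytic.
Per-subject variability multiplies radii and angles by
$1 + 0.05\,Z$ ($Z$ truncated at ±2.5) and jitters modulation phases.

**Axial modulation.**  Local radius and local peak velocity are modulated
independently along each branch ($\pm 15\%$ at 1.5 cycles/length and
$\pm 30\%$ at 2.5 cycles/length, branch-specific phases).  Two reasons:
realism — vessels taper and undulate, and velocity varies along the carotid,
giving WSS a span of roughly 0.8–2.8 Pa, as observed in vivo, rather than a
single value per branch; and identifiability — with constant per-branch
radius and velocity, WSS is an exact function of D ($\propto 1/D$) and the
four-term design matrix is rank-deficient, so the regression the package
exists to fit would be undefined on its own synthetic data.

**Truth maps.**  $D = 2R(s)$, $WSS = 20\,\mu\,v_{peak}(s)/R(s)$ (the
Poiseuille wall gradient in package units), and
$WT = \beta_0 + \beta_1 WSS + \beta_2 D + \beta_3 WSS\,D + \varepsilon$
with $\beta = (1.2, -0.3, 0.08, 0.02)$ by default, chosen so the wall spans
roughly 0.9–1.7 mm — the scale reported for elderly subjects with
asymptomatic plaque (maximum WT around 1.7–2.1 mm).  This choice also keeps
the 0.1 mm physical floor on WT inactive: with a thinner nominal wall the
floor would truncate the noise distribution asymmetrically and visibly
attenuate $\beta_1$ in recovery simulations.  Noise is i.i.d. Gaussian per
vertex (`noise_sd`, default 0.1 mm); an option smooths the noise field over
the mesh (rescaled to `noise_sd`) to emulate spatially correlated noise.
The $\varepsilon$ distribution is an assumption — nothing in the underlying
framework constrains it — and is therefore exposed in the configuration.

**Septum exclusion.**  In the crotch between ICA and ECA the two walls
physically merge into a shared septum thinner than the nominal WT, so *no*
outer surface can realise the linear truth model there.  Lumen vertices
whose offset tip $p + WT\,\hat n$ would land inside the sibling branch's
wall envelope (~3–5% of vertices, confined to the crotch) are excluded from
the subject's maps; the outer wall is then the plain offset of the retained
surface, and the lumen-to-outer distance reproduces the truth WT within
2% + one edge length at every retained vertex.

**Velocity volumes.**  Axial, near-parabolic profiles
$v = v_{peak}(s)\,(1 - r^2/R(s)^2)$ per branch, blended at the junction by
a smooth partition of unity ($w = \max(0, 1-(r/R)^2)^2$); exactness is only
claimed on straight segments.  Voxels default to 0.45 mm isotropic — close
to the 0.7 mm in-plane resolution of the emulated acquisition while
respecting the voxel ≤ radius/3 sampling precondition for the smallest
jittered ECA.  A constant background offset and Gaussian noise can be
added per component.  Steady flow only: the emulated acquisition is
non-gated and time-averaged, so no pulsatility is modelled.

**Reproducibility.**  One master seed; every stream (per-subject mesh,
noise, velocity; bootstrap multisets) is derived from it through
`rng_child_seeds()`, so identical configurations produce bit-identical
cohorts and tables.

# Numerical and statistical choices

* Units are fixed package-wide: mm, cm/s, Pa; the single conversion
  constant (10 s⁻¹ per (cm/s)/mm) lives in one place.
* Spearman's $\rho$ is the Pearson correlation of mid-ranks (average ranks
  for ties, which quantised maps will produce); undefined cases (zero rank
  variance, fewer than 3 complete pairs) are reported missing with a
  reason, not as errors.
* The Fisher z-test reports the mean ± SD of raw $\rho$ but tests
  $\mathrm{atanh}(\rho)$ against zero with a two-sided one-sample t-test;
  $|\rho| = 1$ is clipped at $1-10^{-12}$ with a warning.
* Bootstrap CIs are percentile (2.5th–97.5th of the B replicate values);
  a pair is "significant" when that interval excludes 0.  Correlation and
  regression bootstraps can share one multiset matrix
  (`bootstrap_multisets()`), making the two analyses coherent replicate by
  replicate.
* The linearity check is a lack-of-fit F-test of the straight line against
  decile-binned means at $\alpha = 0.05$; with fewer than 4 distinct bins
  it reports "inadequate data" rather than guessing.
* OLS is QR-based (`stats::lm.fit`); rank deficiency is reported naming
  the collinear term.  $R^2$ is relative to the intercept-only model.

## Calibration of the significance flag

A dedicated simulation (null cohorts of 20 subjects whose WT and WSS maps
are independent smooth random fields, 200 experiments, B = 200) shows the
percentile-CI significance flag to be *conservative*: it fires in ~1% of
null experiments, not 5%.  The cause is structural: bootstrap reweighting
noise enters both averaged maps, so every replicate correlation is
attenuated towards zero relative to the full-cohort value, pulling the
percentile interval towards zero.  The recentred (basic) interval
overcorrects in the opposite direction (30–40% firing), because under a
null with no population map structure the correlation of cohort means has
field-level rather than subject-level degrees of freedom, which subject
resampling cannot estimate.  We keep the percentile rule: a conservative
flag that still fires — as it does for the WT–WSS pair on default
cohorts — is the stronger evidence, but its null firing rate should not be
read as a calibrated 5% error rate.

# Problem sizes used by the shipped validation

Module tests run on coarse meshes (16 vertices/ring, 1.2 mm rings; a few
subjects) in seconds.  The cohort-level validation uses 20 replicate
cohorts of 20 subjects at default resolution with B = 200–1000 bootstrap
replicates, and the end-to-end script `scripts/acceptance.R` runs the full
measured-map pipeline (velocity volumes included) at 20 subjects and
B = 1000.  These sizes were chosen so each simulation's Monte-Carlo error
is well below the effect sizes being checked.

# What the synthetic validation does and does not show

Passing tests demonstrate that the estimators recover known analytic
truths (Poiseuille WSS, cylinder WT/D, exact $\beta$ at zero noise), that
the cohort machinery is statistically sound under the generator's
assumptions (coefficient recovery within 10% with nominal CI coverage at
`noise_sd` = 0.2; cohort-averaged correlations at least as strong as
individual ones), and that the full pipeline is deterministic per seed.
They do not show that real carotid MRI meets those assumptions: the
generator has no partial-volume lumen segmentation error, no registration
error between the anatomical and velocity series, no phase wraps, no
pulsatility, and its WT noise is (optionally smoothed) Gaussian.  Results
on real data will additionally reflect all of those, so the synthetic
recovery rates are best read as upper bounds on pipeline fidelity.

# Known limitations

* The shared geometry is a registered subject mesh, not a mean shape; any
  common vertex set satisfies the three averaging steps, and the choice is
  isolated behind the `shared_geometry` contract.
* The centerline is a centroid-chaining approximation, not a medial axis;
  it is validated for tubular, moderately curved vessels and is not
  intended for pathological topologies.
* WSS near the bifurcation apex inherits both the partition-of-unity
  blending of the synthetic velocity field and normal-direction ambiguity;
  closed-form accuracy is claimed on straight segments only.
* Whether the per-subject correlations of the emulated study used surface
  vertices or image voxels is not determinable from its description;
  vertices are used here.  Likewise the wall-distance could be evaluated
  from lumen or from wall-mesh points; lumen vertices are used.
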