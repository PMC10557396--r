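---
title: "Craniofacial soft-tissue modelling and facial approximation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Craniofacial soft-tissue modelling and facial approximation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cranioface)
```

## The problem

Facial approximation asks: given only a dry skull, what did the face
plausibly look like? The classical manual answer places tissue-depth pegs
at a few dozen anatomical landmarks. `cranioface` implements a fully
computational alternative built on dense geometric morphometrics. Its two
stages are:

1. **Quantification.** From a cohort of paired skull and face surfaces in
   dense point correspondence, learn (a) a field of facial soft-tissue
   depths (FSTDs) over the whole skull envelope, measured along a fixed
   direction per point, and (b) statistical hard-to-soft shape relations
   for the nose and mouth regions, where depths alone are a poor predictor.
2. **Approximation.** For a new dry skull: register the cohort-average
   skull onto it to transfer the dense semilandmarks, inflate the envelope
   by the mean depths, predict nose and mouth shapes by regression, place
   them on the envelope by boundary-curve alignment, fit a facial
   statistical shape model (SSM) to the assembled coarse face to fill in
   eyes, ears and missing geometry, and finally blend the SSM fit back
   toward the coarse soft tissues by Laplacian mesh deformation.

## Models and procedures

### FSTD field

For skull point $s_i$ with fixed unit direction $n_i$ (the vertex normal of
the cohort-average skull, identical for every specimen), the depth $d_i$ is
the ray distance to the first intersection with the facial surface, and the
implied face point is $h_i = s_i + d_i\,n_i$. Keeping $n_i$ constant across
specimens makes per-point depth distributions comparable; `measure_fstd()`
flags rays that miss within `max_depth` (default 60 mm, a generous bound on
head soft tissue) as missing, and `fstd_statistics()` reports per-point
means and sample standard deviations (ddof = 1) with availability counts.
`build_envelope()` applies the mean depths to a new skull; missing means
are imputed by inverse-distance-weighted averaging of the 8 nearest
measured points.

### Shape statistics

`gpa()` performs generalized Procrustes analysis (translation, rotation,
optionally unit-centroid-size scaling), `pca_shapes()` the subsequent PCA;
the retained dimension is the smallest reaching a cumulative variance
threshold (default 0.95 everywhere, the paper-style "determined from the
cumulative proportion" made concrete). `two_block_pls()` computes two-block
partial least squares as the SVD of the between-block cross-covariance of
column-centred data, with per-axis score correlations, percent squared
covariance (summing to 100), and the RV coefficient
$\mathrm{RV} = \operatorname{tr}(S_{XY}S_{YX}) /
\sqrt{\operatorname{tr}(S_{XX}^2)\operatorname{tr}(S_{YY}^2)}$.
`pls_permutation_test()` permutes specimen rows of block 2 and uses the
add-one estimator $p = (1 + \#\{stat_{perm} \ge stat_{obs}\})/(1+B)$, so
$p = 0$ is unattainable and the minimum is $1/(B+1)$. PLS axis signs follow
a fixed convention (first non-zero block-1 loading positive) so extreme
shapes (`pls_extreme_shapes()`) are reproducible.

### Organ regression

Nose and mouth soft-tissue shapes are predicted from the nasal and oral
hard-tissue shapes through a ridge map between PC scores,
$M = \arg\min \lVert M\beta_h - \beta_s\rVert^2 + \eta^2\lVert M\rVert^2$,
solved in closed form. $\eta$ defaults to a leave-one-out grid search over
$\{0, 0.01, 0.1, 1, 10\}$ since no formula is given for it in the source
method. Predictions are emitted in shape space (unit size, alignment-free);
metric placement is deliberately deferred to assembly.

**Shape vs form.** By default the organ machinery operates on
unit-centroid-size Procrustes shape coordinates. Note that unit-size
scaling and per-specimen optimal rotation are *nonlinear* in any generating
latent variables, so an exactly linear synthetic cohort is recovered only
to second order in the variation scale. A `with_scaling = FALSE` route
keeps millimetre form coordinates, under which exact linear cohorts are
recovered exactly; the tests exercise both.

### Registration

Template-to-specimen correspondence uses a hybrid of thin-plate-spline
warping on landmarks (3D kernel $U(r)=r$; exact interpolation at zero
regularization) followed by optimal-step non-rigid ICP with per-vertex
affine transforms under an edge-difference stiffness penalty. Defaults
chosen here (the cited NICP method is parameter-free in the source):
stiffness schedule $\{50, 20, 10, 5, 2\}$ ($\{20, 8, 2\}$ inside the
approximation pipeline, where the TPS initialization is already close),
per-stage convergence when the mean update norm falls below $10^{-3}$,
landmark soft-constraint weight 10 decaying to 1 in the final stage, and
correspondence pruning at distance $> \max(4\times\mathrm{median},\,
\mathrm{median\ target\ edge\ length})$ or normal disagreement $> 60°$.
The absolute floor on the pruning threshold matters: without it, a
nearly converged registration prunes almost all of its own (excellent)
correspondences and drifts away again.

### Assembly

Component placement (`place_component()`) resamples both boundary loops to
m = 100 points by normalized arc length and searches all cyclic offsets ×
both directions (200 candidates) for the similarity transform minimizing
the boundary RMS — the correspondence rule is unstated in the source, and
this exhaustive search is the package's choice. Predicted organ shapes are
pre-scaled to the target rim's centroid size before alignment (flagged as
an interpretation: the source never says how shape-space organs acquire an
initial metric scale).

SSM fitting solves a ridge least-squares problem restricted to the
corresponded rows of the PC basis ($\lambda$ defaults to $10^{-3}\times$
the leading eigenvalue) and reconstructs all points, which is what fills
in the eyes and ears: those regions are produced only by SSM completion,
never by regression. The final Laplacian refinement minimizes
$\sum_i \lVert \delta(g_i) - \delta(v_i) \rVert^2 +
w^2 \sum_j \lVert l_j - g_j \rVert^2$ in one sparse solve per coordinate;
the anchor weight $w$ (default 1, configurable; $w \approx 10^3$
approximates hard constraints) is an explicit parameter the source's
formulation leaves implicit. The Laplacian is uniform (graph) by default
with cotangent weights optional.

Correspondences into the SSM frame come from ray casting: each skull
envelope point's fixed ray hits the coarse envelope (at its own $h_i$, by
construction) and the deformed average face; the nearest average-face
vertex index pairs the two, and a closed-form similarity transform maps
the coarse face into the SSM frame.

## The synthetic cohort

No clinical data ships with the package. `generate_cohort()` emits paired
skull/face meshes from a stated world:

- **Base head**: a sphere of radius 80 mm modulated by fixed smooth
  low-order angular modes; nasal and oral patches carved at fixed solid
  angles. Crude by design — it exercises ray casting, registration, patch
  topology and boundary loops, not anatomy.
- **Cohort**: default n = 48 specimens (mirroring a typical adult CT
  cohort; tests use smaller n), per-specimen coefficients on the global
  modes (SDs 2 … 0.4 mm), a smooth depth field with mean 9 mm plus a
  ±1.5 mm spatial pattern, a per-subject scalar offset (SD 0.8 mm) and
  per-point noise (SD 0.3 mm).
- **Organ coupling**: latent vectors $z$ (dimension 2 per organ) drive the
  hard-tissue patch displacement; the soft patch is displaced by
  $\rho z + \sqrt{1-\rho^2}\,\varepsilon$ on matching mode shapes
  (default $\rho = 0.8$, scale 1.5 mm, independent noise 0.2 mm). The soft
  displacement is anchored to the core head rather than the displaced
  skull, so $\rho$ — and only $\rho$ — sets the hard↔soft covariation; at
  $\rho = 1$ with zero organ noise the patch FSTD reduces exactly to the
  depth field.
- **Landmarks** sit at fixed parametric directions, giving perfect
  cross-specimen homology — an idealization relative to manual
  landmarking. Global head modes are a second, legitimate coupling channel
  between hard and soft blocks (tissue rides on bone); null-hypothesis
  tests of the organ channel disable them.

What a green test establishes: the numerics (GPA, PLS, regression, SSM,
Laplacian, registration) are correct against independent oracles, and the
assembled pipeline recovers individual identity when inter-individual
variation dominates noise. What it does not establish: performance on real
craniofacial anatomy, robustness to landmarking error, segmentation noise,
or demographic structure (sex/age/BMI), none of which the generator
emulates.

## Numerical choices and degenerate inputs

- GPA converges on mean-shape change $< 10^{-10}$; the reported mean is the
  plain average of the aligned configurations.
- TPS systems get one step of iterative refinement, and kernel distances
  are evaluated exactly per control point (the expanded dot-product form
  loses ~7 digits near control points).
- Rank decisions use relative singular-value thresholds ($10^{-12}$);
  identical-face SSMs report d = 0 and return the mean.
- Reflection guards (Kabsch–Umeyama) keep every fitted rotation proper.
- Nearest-point projection is exact point-to-triangle with ties broken by
  lowest face index; outward normal orientation is fixed by coherent
  winding propagation plus a centroid majority vote.
- Degenerate inputs (coincident porions, collinear TPS sources, zero-size
  configurations, empty meshes, anchor-free components) raise typed errors
  naming the offending stage.

## Known limitations

- Brute-force spatial queries (no BVH): fine at the package's working
  scales (≤ ~5k vertices), quadratic beyond.
- Surface reconstruction assumes near-planar or star-shaped point clouds;
  general topology would need a true pivoting-ball or Poisson
  reconstruction.
- The permutation test permutes whole specimens only (no restricted
  permutation structure).
- `pipeline_loocv` retrains everything per fold but reuses the cohort's
  built-in dense correspondence for training; only the held-out skull is
  re-registered from scratch, matching how a real deployment would consume
  an already-corresponded training database.
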