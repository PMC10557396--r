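# cranioface

Craniofacial soft-tissue modelling and computerized facial approximation
in R.

`cranioface` is for researchers in physical anthropology, forensic science
and craniofacial biology who want to (a) quantify the statistical
relationship between skull and face surfaces in a corresponded cohort and
(b) generate an approximated face from a dry-skull mesh. It implements a
dense, landmark-free-at-scale pipeline:

- **FSTD fields** — facial soft-tissue depths `d_i` measured from every
  skull landmark/semilandmark `s_i` along a fixed per-point direction
  `n_i` (the cohort-average skull's vertex normals), so the implied face
  point is `h_i = s_i + d_i n_i`.
- **Geometric morphometrics** — generalized Procrustes analysis, shape
  PCA, two-block partial least squares (SVD of the between-block
  cross-covariance), RV coefficients and seeded permutation tests.
- **Organ regression** — ridge maps `M = argmin ‖M βʰ − βˢ‖² + η²‖M‖²`
  from nasal/oral hard-tissue PC scores to nose/mouth soft-tissue PC
  scores.
- **Registration** — 3D thin-plate splines (kernel `U(r) = r`), optimal-step
  non-rigid ICP with a stiffness schedule, and closed-form
  Kabsch–Umeyama similarity alignment.
- **Coarse-to-fine assembly** — envelope inflation by mean depths,
  boundary-curve placement of predicted organs, statistical-shape-model
  fitting `argmin ‖U_s β − (tp − F̄)‖² + λ²‖β‖²` with reconstruction
  `Q(β) = F̄ + Σ μ_i b_i`, and Laplacian refinement
  `Σ‖δ(g_i) − δ(v_i)‖² + w² Σ‖l_j − g_j‖²`.
- **Evaluation** — Procrustes + dense nearest-point resemblance on a
  16 + 59-point scheme, top-k recognition rates, and an end-to-end
  leave-one-out driver.
- **Synthetic cohorts** — paired skull/face meshes with a known depth
  field and a tunable linear hard↔soft organ coupling (`ρ`), so the whole
  pipeline is testable without clinical data.

## Worked example

```r
library(cranioface)

co <- generate_cohort(cohort_spec(n = 8, seed = 42, subdivisions = 3))
skulls <- lapply(co$skulls, `[[`, "vertices")
faces  <- lapply(co$faces,  `[[`, "vertices")

# train on specimens 2..8, hold out specimen 1 as the "dry skull"
model <- train_fa_model(skulls[-1], faces[-1], co$template_faces,
                        co$skull_labels, co$face_labels,
                        co$landmark_idx, co$eval_idx)
#> <cf_fa_model> trained on 7 specimens; 642 skull points (610 envelope), SSM d = 4
sprintf("cohort FSTD: %.2f +/- %.2f mm", model$fstd$cohort_mean,
        model$fstd$cohort_sd)
#> "cohort FSTD: 9.23 +/- 0.80 mm"

ap <- approximate_face(co$skulls[[1]], co$skull_landmarks[[1]], model)
rs <- resemblance(ap$mesh, co$faces[[1]],
                  ap$config[co$eval_idx, ], faces[[1]][co$eval_idx, ])
```

The held-out reconstruction gives a mean dense error of **1.14 mm**
against the true face versus **1.64 mm** for the cohort-mean-face
baseline (Procrustes distance 10.58 on the 75 evaluation points, form
space): the skull-specific information genuinely improves on the average
face. The nose hard↔soft covariation in the same cohort:

```r
nasal <- which(co$skull_labels$labels == "nasal")
nose  <- which(co$face_labels$labels == "nose")
X <- do.call(rbind, lapply(skulls, function(p) as.vector(t(p[nasal, ]))))
Y <- do.call(rbind, lapply(faces,  function(p) as.vector(t(p[nose, ]))))
pls <- two_block_pls(X, Y)
pt  <- pls_permutation_test(X, Y, n_perm = 999, seed = 1)
#> nose 2B-PLS: axis-1 r = 0.901 (99.3% of squared covariance),
#>              RV = 0.805, p = 0.006
```

The axis-1 correlation of 0.90 reflects the generator's latent coupling
(`ρ = 0.8` plus shared global head modes); the permutation p-value uses
the add-one estimator, so its smallest attainable value with 999
permutations is 0.001.

A full leave-one-out evaluation, including top-k recognition:

```r
rep <- pipeline_loocv(co, k = 1)
rep$recognition   # percent of specimens whose true face ranks first
rep$table         # per-specimen Procrustes / dense-mm / baseline / rank
```

## Command line

A thin wrapper is installed at `inst/cli/cranioface`:

```sh
cranioface simulate --out cohort/ --n 8 --seed 42 --subdivisions 3
cranioface train --cohort cohort/ --out model/
cranioface approximate --skull cohort/skull_01.ply \
    --landmarks cohort/skull_01_landmarks.csv --model model/ --out face.ply
cranioface loocv --cohort cohort/ --out report/
```

Every output directory receives a `run_config.json` provenance stamp;
all stochastic steps take `--seed`.

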