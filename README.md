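# radssm

Statistical shape modelling and shape completion for the distal radius.

## The problem

3D planning of a corrective osteotomy for a malunited distal radius normally
uses the mirrored contralateral radius as the reconstruction template. In
roughly one patient in ten no healthy contralateral radius exists. `radssm`
implements the alternative: a **shape completion model** that predicts the
healthy distal 12% of a radius from the proximal 88% left intact by the
fracture, using only a statistical shape model (SSM) of healthy bones.

It is aimed at researchers in orthopaedic 3D planning and statistical shape
modelling who want a self-contained, fully testable implementation of the
pipeline — including a synthetic bone generator with known ground truth, so
every stage can be validated without clinical CT data.

## The model

Corresponded bone surfaces `x ∈ R^(3n)` (vertex coordinates, mm) follow the
linear-Gaussian shape model

    x = x̄ + Σ_k c_k √λ_k b_k,   c_k ~ N(0, 1)

with mean `x̄` and principal components `(λ_k, b_k)` from PCA of
GPA-aligned training shapes (rigid alignment only — size is clinically
meaningful). For completion the covariance is augmented with an isotropic
Gaussian kernel `scale · exp(−‖x−x′‖²/σ²) · I₃` (low-rank via Nyström), and
the distal part is predicted by GP posterior regression from the observed
proximal vertices:

    α = (QᵀQ + noise·I)⁻¹ Qᵀ (y − x̄_obs),   x̂ = x̄ + Q_full α

where `Q` is the scaled basis restricted to observed coordinates and `noise`
is the ridge magnitude. The three hyperparameters (noise, sigma, scale) are
grid-searched over the standard 4 × 6 × 3 grid.

Prediction error is reported as surface accuracy (mean closest-point
distance), maximum Hausdorff distance, per-vertex heatmaps, and the clinical
six degrees of freedom of the distal segment: radial inclination (φx), volar
tilt (φz), axial rotation (φy), dorsal shift (Δx), radial shift (Δz),
lengthening (Δy), plus the convention-free 3D angle and 3D distance.

## Worked example

```r
library(radssm)

# synthetic population of 40 bones with known latent shape modes
tpl <- make_template(n_vertices = 800)
pop <- generate_population(tpl, n_shapes = 40, noise_sd_mm = 0.3, seed = 1)

# shape model from the first 30 shapes (already corresponded by construction)
model <- build_ssm(gpa(pop$meshes[1:30])$aligned)
glance(model)
#> # A tibble: 1 x 5
#>   n_vertices n_components n_training total_variance n_components_95
#>        <dbl>        <int>      <int>          <dbl>           <int>
#> 1        794           29         30         10046.               3

# complete the proximal 88% of an unseen bone
unseen <- pop$meshes[[35]]
cuts   <- cut_by_length_fraction(unseen, "y", 0.88)
prox   <- submesh(unseen, cuts$proximal)
res    <- complete_shape(model, prox, kernel_params(noise = 5, sigma = 100, scale = 5))

accuracy(res$predicted, unseen)        # mean surface distance, mm
#> [1] 0.2983993
hausdorff_max(res$predicted, unseen)   # worst-case distance, mm
#> [1] 2.84513

tidy(clinical_error(res$predicted, unseen))   # 6-DOF error of the distal 12%
#> # A tibble: 1 x 9
#>   phi_x phi_z phi_y delta_x delta_y delta_z angle_3d dist_3d gimbal_warning
#>   <dbl> <dbl> <dbl>   <dbl>   <dbl>   <dbl>    <dbl>   <dbl> <lgl>
#> 1  2.86  2.32 -3.05   -1.07  -0.785   0.440     4.81    1.40 FALSE
```

The accuracy (0.30 mm) is the mean distance from the predicted surface to the
true bone; the 6-DOF row says the predicted distal segment is tilted a few
degrees and displaced ~1.4 mm from the truth — the quantities a surgical
planner would act on.

The full study pipeline (generate → split 8:1:1 → two-pass model build →
grid search → test evaluation → clinical errors) is one call:

```r
res <- run_pipeline(pipeline_config(seed = 1, out_dir = "results"))
```

A thin command-line wrapper with `synth`, `align`, `correspond`, `build`,
`grid-search`, `complete`, `evaluate`, `clinical` and `run-all` subcommands
ships in `inst/cli/radssm.R`.

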