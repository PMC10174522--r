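# eitdct

Structural-prior reconstruction for 2D thoracic electrical impedance
tomography (EIT), built around a lung-masked discrete cosine basis.

## The problem and who this is for

EIT monitors regional lung ventilation at the bedside by reconstructing
internal conductivity changes from boundary voltages (16 electrodes,
adjacent stimulation/measurement, 208 values per frame). The inverse
problem is ill-posed, and generic regularization yields blurred images that
are hard to align with anatomy. This package is for researchers studying
how anatomical priors from morphological imaging (CT) change EIT image
quality: it implements the full simulation tool chain — FEM forward
modelling, phantoms, reconstruction, baselines, metrics — so the comparison
can be run end to end on synthetic thorax data.

The core method represents the image in a truncated 2D DCT basis (15 × 15
frequencies), masks every basis member pixelwise with a CT-derived weight
field *P* (a binary lung **contour prior**, or a graded **detail prior**
with w = HU/(−1000): air −1000 HU → 1, atelectasis ≈ 0 HU → 0), projects
the masked stack onto the inverse FEM mesh (**K**), and solves one
Tikhonov-regularized Gauss-Newton step in coefficient space:

    x̂ = (J_DCTᵀ J_DCT + λ² I)⁻¹ J_DCTᵀ y,   J_DCT = J·K,   H = Σⱼ C(p,q)ⱼ x̂ⱼ

with λ calibrated so the reconstruction's noise figure is 0.5. The restored
image is exactly zero wherever the prior weight is zero. Comparison
baselines: element-space one-step Gauss-Newton with an inhomogeneous
background linearization (lung 0.5 / background 1), and a GREIT-style
trained linear reconstructor.

## Worked example

```r
library(eitdct)

scene  <- make_thorax_scene(128, 128, seed = 1)       # thorax + lungs + CT surrogate
proto  <- adjacent_protocol(16)
fwd    <- build_mesh(scene$thorax_polygon, 16, 20000) # data-generating mesh
inv    <- build_mesh(scene$thorax_polygon, 16, 3000)  # reconstruction mesh
fwd    <- set_conductivity(fwd, scene$sigma_baseline_fun)
inv    <- set_conductivity(inv, scene$sigma_baseline_fun)

state  <- apply_atelectasis(scene, 0.25)              # 25% dorsal atelectasis
target <- set_conductivity(fwd, state$sigma_target_fun)
y      <- simulate_measurement(target, fwd, proto, noise_fraction = 0.25, seed = 7)

J      <- compute_jacobian(inv, protocol = proto, normalized = TRUE)
prior  <- make_detail_prior(state$ct_surrogate, state$lung_mask)
rec    <- reconstruct_pipeline(inv, prior, J, y)
rec
#> <eit_recon dct_detail> lambda = 0.02515, NF = 0.5000, 225 coefficients
glance(rec)
#> # A tibble: 1 × 4
#>   method     lambda noise_figure n_coefficients
#>   <chr>       <dbl>        <dbl>          <int>
#> 1 dct_detail 0.0251        0.500            225
```

`lambda` is the calibrated Tikhonov weight, `noise_figure` the achieved
noise amplification (target 0.5 ± 1%), and the 225 coefficients weight the
masked cosine members. `autoplot(rec)` shows the restored image: negative
(conductivity decrease, i.e. air ingress) over the ventilated lung, exactly
zero over the atelectatic slab and outside the lungs. The full four-method
comparisons are one call each:

```r
cfg <- study_config(seed = 1)        # 5 patterns / 11 atelectasis fractions,
ps  <- run_pattern_study(cfg)        # 25% noise, 10 seeds per case
glance(ps)                           # mean l2 per method + % improvements
autoplot(ps)
```

A thin CLI over the same functions is in `inst/scripts/run-study.R`.

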