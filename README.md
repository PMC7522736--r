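# qsmtfir

Total field inversion for quantitative susceptibility mapping (QSM) with
spatially adaptive shadow-suppressing regularization.

## The problem

QSM inverts the measured MRI field perturbation for the underlying tissue
magnetic susceptibility χ (ppm).  The field of a susceptibility
distribution is `f = d * χ`, a convolution with the unit dipole whose
frequency response `D(k) = 1/3 − (k·b0)²/|k|²` vanishes on a cone and at
`k = 0`, making the inversion ill-posed.  Working from the *total* field —
without first removing the background field of air (≈ 9 ppm) and bone
(≈ −2 ppm) — avoids background-removal errors and mask erosion, but
invites *shadow artifacts*: smooth error bowls from field components that
the model attributes to the wrong side of the brain boundary.

`qsmtfir` implements the TFIR estimator

```
χ* = argmin_χ  ½‖w (f − d*χ)‖₂² + λ₁‖M_G ∇χ‖₁ + λ₂‖r L χ‖₂²
```

where `w` is an SNR weight, `M_G` a binary mask that exempts the
strongest magnitude edges from the total-variation penalty, `L` a
spherical-mean-value (SMV) low-pass filter of radius `k`, and
`r = exp(−|τ · L R2*|)` a weight computed from the R2\* relaxation map:
low-frequency susceptibility is penalized heavily where R2\* (hence the
expected susceptibility contrast) is low, and left free where R2\* is
high — including signal-free air, whose apparent R2\* is very large.
Plain total field inversion (`λ₂ = 0`), a least-norm variant (`r` = the
binary mask, `L` = identity) and a linear SMV-filtered local-field
comparator are available as solver variants.

The package also provides NIfTI I/O, multi-echo GRE fitting (R2\*, total
field, noise weight), synthetic brain / gadolinium / shadow phantom
generators with a forward signal simulator, and evaluation metrics
(masked RMSE, ROI statistics, regression slope, shadow index, binned
susceptibility–1/r correlation).  It is aimed at method developers who
want a transparent, fully synthetic-testable reference implementation of
adaptive total field inversion.

## Worked example

Reconstruct a shadow-contaminated synthetic brain and compare TFIR with
plain total field inversion:

```r
library(qsmtfir)

spec <- phantom_spec("shadow", seed = 1)      # 32³ brain + smooth field bowl
ph   <- make_shadow_phantom(spec)

grid <- spec$grid
w  <- scalar_volume(ph$head_mask$values, grid, "weight")
mg <- edge_mask(scalar_volume(exp(-0.02 * ph$r2star_true$values), grid),
                ph$head_mask, edge_fraction = 0.1)
r  <- weight_mask_r(ph$r2star_true, tau_s = 0.05, L = smv_kernel(grid, 1))

fit   <- reconstruct(ph$f_contaminated, w, ph$head_mask, mg, r,
                     tfir_params(lambda1 = 1e-3, lambda2 = 0.1))
plain <- reconstruct(ph$f_contaminated, w, ph$head_mask, mg, r,
                     tfir_params(lambda1 = 1e-3, variant = "tfi_plain"))
fit
cat(sprintf("in-brain RMSE:  TFIR %.4f ppm   plain TFI %.4f ppm\n",
            rmse(fit$chi,  ph$chi_true, ph$brain_mask),
            rmse(plain$chi, ph$chi_true, ph$brain_mask)))
cat(sprintf("shadow index:   TFIR %.1f ppb    plain TFI %.1f ppb\n",
            shadow_index(fit$chi,  ph$head_mask),
            shadow_index(plain$chi, ph$head_mask)))
```

```
<recon_result: 13 outer iterations, converged, objective 11.6558 -> 1.20511>
in-brain RMSE:  TFIR 0.0586 ppm   plain TFI 9.4738 ppm
shadow index:   TFIR 10.6 ppb    plain TFI 280.5 ppb
```

The contaminated field carries both a 9 ppm air background and an
injected smooth error bowl.  Without the adaptive L2 term the inversion
is unregularized along its null directions and fails outright
(9.47 ppm RMSE, shadow index 281 ppb); TFIR recovers the brain to
0.059 ppm and suppresses the shadow by more than an order of magnitude.

The same pipeline is available from the shell:

```sh
Rscript inst/cli/qsmtfir.R simulate --scenario shadow --outdir sim --seed 1
Rscript inst/cli/qsmtfir.R recon --field sim/field_contaminated.nii.gz \
    --mask sim/head_mask.nii.gz --r2star sim/r2s.nii.gz \
    --lambda1 1e-3 --lambda2 0.1 --tau 0.05 --k-mm 1 \
    --variant tfir --out chi.nii.gz --log recon.json
Rscript inst/cli/qsmtfir.R metrics --chi chi.nii.gz \
    --truth sim/chi_true.nii.gz --mask sim/head_mask.nii.gz --out metrics.csv
```

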