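# Small deterministic fixtures shared across test files.

random_volume <- function(grid, seed = 1, kind = "generic", scale = 1) {
  set.seed(seed)
  scalar_volume(array(stats::rnorm(prod(grid$dims), sd = scale), grid$dims),
                grid, kind)
}

unit_mask <- function(grid) {
  scalar_volume(array(1, grid$dims), grid, "mask")
}

# tiny brain-like phantom for fast solver tests
small_shadow_spec <- function(seed = 1, ...) {
  phantom_spec("shadow", seed = seed, ...)
}

# standard solver inputs derived from a phantom's R2* truth: binary-mask
# data weight, late-echo-magnitude edge masks, adaptive weight mask
recon_inputs <- function(r2star, mask, tau_s = 0.05, k_mm = 1,
                         edge_fraction = 0.1) {
  grid <- mask$grid
  mag <- scalar_volume(exp(-0.02 * r2star$values), grid, "generic")
  list(w = scalar_volume(mask$values, grid, "weight"),
       mg = edge_mask(mag, mask, edge_fraction),
       r = weight_mask_r(r2star, tau_s, smv_kernel(grid, k_mm)))
}
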