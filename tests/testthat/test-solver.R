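# shared small fixture for solver tests
solver_fixture <- local({
  g <- voxel_grid(c(16, 16, 16))
  set.seed(5)
  chi_t <- scalar_volume(array(0.1 * rnorm(16^3), c(16, 16, 16)), g,
                         "susceptibility_ppm")
  f <- apply_kspace(dipole_kernel(g), chi_t)
  mask <- unit_mask(g)
  w <- scalar_volume(array(1, c(16, 16, 16)), g, "weight")
  mag <- scalar_volume(array(runif(16^3), c(16, 16, 16)), g)
  mg <- edge_mask(mag, mask, 0.1)
  r2s <- scalar_volume(array(runif(16^3, 0, 50), c(16, 16, 16)), g,
                       "r2star_per_s")
  r <- weight_mask_r(r2s, 0.05, smv_kernel(g, 1))
  list(g = g, chi_t = chi_t, f = f, mask = mask, w = w, mg = mg,
       r2s = r2s, r = r)
})

test_that("objective terms match a brute-force voxel-loop oracle", {
  g <- voxel_grid(c(8, 8, 8))
  set.seed(17)
  n <- 8
  chi <- random_volume(g, 17, "susceptibility_ppm", scale = 0.1)
  f <- random_volume(g, 18, "field_ppm", scale = 0.1)
  wv <- array(runif(n^3, 0.2, 1.5), g$dims)
  w <- scalar_volume(wv, g, "weight")
  mgv <- lapply(1:3, function(i)
    scalar_volume(array(rbinom(n^3, 1, 0.8), g$dims), g, "mask"))
  rv <- array(runif(n^3, 0.1, 1), g$dims)
  r <- scalar_volume(rv, g, "weight")
  p <- tfir_params(lambda1 = 0.02, lambda2 = 0.3, smv_radius_mm = 1)
  got <- objective(chi, f, w, mgv, r, p)

  # independent path: dipole convolution through the periodic point-spread
  # function by explicit spatial summation, gradients by index arithmetic,
  # SMV by explicit neighbor averaging
  psf <- Re(stats::fft(dipole_kernel(g)$values, inverse = TRUE)) / n^3
  conv <- array(0, g$dims)
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    acc <- 0
    for (a in 1:n) for (b in 1:n) for (cc in 1:n) {
      acc <- acc + psf[(i - a) %% n + 1, (j - b) %% n + 1,
                       (k - cc) %% n + 1] * chi$values[a, b, cc]
    }
    conv[i, j, k] <- acc
  }
  data_oracle <- 0.5 * sum((wv * (f$values - conv))^2)
  tv_oracle <- 0
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    tv_oracle <- tv_oracle +
      abs(mgv[[1]]$values[i, j, k] *
            (chi$values[i %% n + 1, j, k] - chi$values[i, j, k])) +
      abs(mgv[[2]]$values[i, j, k] *
            (chi$values[i, j %% n + 1, k] - chi$values[i, j, k])) +
      abs(mgv[[3]]$values[i, j, k] *
            (chi$values[i, j, k %% n + 1] - chi$values[i, j, k]))
  }
  tv_oracle <- p$lambda1 * tv_oracle
  offs <- rbind(c(0, 0, 0), c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  l2_oracle <- 0
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    acc <- 0
    for (q in 1:7)
      acc <- acc + chi$values[(i + offs[q, 1] - 1) %% n + 1,
                              (j + offs[q, 2] - 1) %% n + 1,
                              (k + offs[q, 3] - 1) %% n + 1] / 7
    l2_oracle <- l2_oracle + (rv[i, j, k] * acc)^2
  }
  l2_oracle <- p$lambda2 * l2_oracle
  expect_equal(got$data, data_oracle, tolerance = 1e-10)
  expect_equal(got$tv, tv_oracle, tolerance = 1e-10)
  expect_equal(got$l2, l2_oracle, tolerance = 1e-10)
  expect_equal(got$total, data_oracle + tv_oracle + l2_oracle,
               tolerance = 1e-10)
})

test_that("objective special cases: zero map and data-consistent truth", {
  fx <- solver_fixture
  zero <- scalar_volume(array(0, fx$g$dims), fx$g, "susceptibility_ppm")
  p <- tfir_params()
  at0 <- objective(zero, fx$f, fx$w, fx$mg, fx$r, p)
  expect_equal(at0$total, 0.5 * sum((fx$w$values * fx$f$values)^2),
               tolerance = 1e-12)
  expect_equal(at0$tv, 0)
  expect_equal(at0$l2, 0)
  p0 <- tfir_params(lambda1 = 0, lambda2 = 0)
  at_truth <- objective(fx$chi_t, fx$f, fx$w, fx$mg, fx$r, p0)
  expect_lt(at_truth$data, 1e-12 * at0$data)
})

test_that("zero field with zero start is a one-iteration fixed point", {
  fx <- solver_fixture
  zf <- scalar_volume(array(0, fx$g$dims), fx$g, "field_ppm")
  rec <- reconstruct(zf, fx$w, fx$mask, fx$mg, fx$r, tfir_params())
  expect_true(all(rec$chi$values == 0))
  expect_equal(rec$n_outer, 1L)
  expect_true(rec$converged)
})

test_that("lambda2 = 0 makes TFIR and plain TFI bitwise identical", {
  fx <- solver_fixture
  pa <- tfir_params(lambda1 = 1e-3, lambda2 = 0, variant = "tfir",
                    max_outer = 5)
  pb <- tfir_params(lambda1 = 1e-3, lambda2 = 0.7, variant = "tfi_plain",
                    max_outer = 5)
  ra <- reconstruct(fx$f, fx$w, fx$mask, fx$mg, fx$r, pa)
  rb <- reconstruct(fx$f, fx$w, fx$mask, fx$mg, fx$r, pb)
  expect_identical(ra$chi$values, rb$chi$values)
})

test_that("tau = 0 with sub-voxel k reduces TFIR to the least-norm variant", {
  fx <- solver_fixture
  r0 <- weight_mask_r(fx$r2s, 0, smv_kernel(fx$g, 0.4))
  pc <- tfir_params(lambda1 = 1e-3, lambda2 = 0.05, tau_s = 0,
                    smv_radius_mm = 0.4, variant = "tfir", max_outer = 5)
  pd <- tfir_params(lambda1 = 1e-3, lambda2 = 0.05, variant = "ln_qsm",
                    max_outer = 5)
  rc <- reconstruct(fx$f, fx$w, fx$mask, fx$mg, r0, pc)
  rd <- reconstruct(fx$f, fx$w, fx$mask, fx$mg, r0, pd)
  expect_lt(max(abs(rc$chi$values - rd$chi$values)), 1e-8)
})

test_that("the SMV-filtered comparator erodes its mask and runs", {
  g <- voxel_grid(c(20, 20, 20))
  set.seed(6)
  chi_t <- scalar_volume(array(0.1 * rnorm(20^3), c(20, 20, 20)), g,
                         "susceptibility_ppm")
  f <- apply_kspace(dipole_kernel(g), chi_t)
  mask <- unit_mask(g)
  w <- scalar_volume(array(1, c(20, 20, 20)), g, "weight")
  mg <- edge_mask(scalar_volume(array(1, c(20, 20, 20)), g), mask, 0)
  r <- scalar_volume(array(1, c(20, 20, 20)), g, "weight")
  p <- tfir_params(lambda1 = 1e-3, variant = "medi_smv_linear",
                   medi_smv_radius_mm = 3, max_outer = 3)
  rec <- reconstruct(f, w, mask, mg, r, p)
  expect_s3_class(rec, "recon_result")
  expect_true(all(diff(rec$objective_trace) <=
                    1e-6 * abs(rec$objective_trace[-length(rec$objective_trace)])))
  # a tiny mask vanishes entirely under erosion
  tiny <- array(0, c(20, 20, 20)); tiny[10, 10, 10] <- 1
  expect_error(
    reconstruct(f, scalar_volume(tiny, g, "weight"),
                scalar_volume(tiny, g, "mask"), mg, r, p),
    "vanished")
})

test_that("reconstruction is scale covariant when the TV term is off", {
  fx <- solver_fixture
  p <- tfir_params(lambda1 = 0, lambda2 = 0.05, max_outer = 5)
  r1 <- reconstruct(fx$f, fx$w, fx$mask, fx$mg, fx$r, p)
  f3 <- scalar_volume(3 * fx$f$values, fx$g, "field_ppm")
  r3 <- reconstruct(f3, fx$w, fx$mask, fx$mg, fx$r, p)
  expect_equal(r3$chi$values, 3 * r1$chi$values, tolerance = 1e-6)
})

test_that("degenerate solver inputs raise", {
  fx <- solver_fixture
  zw <- scalar_volume(array(0, fx$g$dims), fx$g, "weight")
  expect_error(reconstruct(fx$f, zw, fx$mask, fx$mg, fx$r, tfir_params()),
               "zero everywhere")
  badr <- scalar_volume(array(0, fx$g$dims), fx$g, "weight")
  expect_error(reconstruct(fx$f, fx$w, fx$mask, fx$mg, badr, tfir_params()),
               "\\(0, 1\\]")
})

test_that("grid_search reports RMSE consistently and deterministically", {
  spec <- small_shadow_spec(seed = 1)
  ph <- make_shadow_phantom(spec)
  grid <- spec$grid
  mask <- ph$head_mask
  bundle <- list(
    f = ph$f_contaminated,
    w = scalar_volume(mask$values, grid, "weight"),
    mask = mask,
    mg_masks = edge_mask(
      scalar_volume(exp(-0.02 * ph$r2star_true$values), grid), mask, 0.1),
    r2star = ph$r2star_true,
    eval_mask = ph$brain_mask
  )
  base <- tfir_params(lambda1 = 1e-3, max_outer = 10)
  # single combination equals a direct reconstruction + rmse call
  tab1 <- grid_search(ph$chi_true, bundle, 0.1, 0.05, 1, base)
  expect_equal(nrow(tab1), 1)
  expect_true(tab1$optimal)
  L <- smv_kernel(grid, 1)
  r <- weight_mask_r(ph$r2star_true, 0.05, L, mask)
  p1 <- base; p1$lambda2 <- 0.1; p1$tau_s <- 0.05; p1$smv_radius_mm <- 1
  direct <- rmse(reconstruct(bundle$f, bundle$w, mask, bundle$mg_masks, r,
                             p1)$chi,
                 ph$chi_true, ph$brain_mask)
  expect_equal(tab1$rmse, direct, tolerance = 1e-12)
  # under background contamination the regularized setting wins over
  # lambda2 = 0, and candidate order does not change the argmin
  tab2 <- grid_search(ph$chi_true, bundle, c(0, 0.1), 0.05, 1, base)
  expect_equal(tab2$lambda2[tab2$optimal], 0.1)
  tab2r <- grid_search(ph$chi_true, bundle, c(0.1, 0), 0.05, 1, base)
  expect_equal(tab2r$lambda2[tab2r$optimal], 0.1)
  expect_equal(sort(tab2$rmse), sort(tab2r$rmse), tolerance = 1e-12)
  expect_error(grid_search(ph$chi_true, bundle, numeric(0), 0.05, 1, base),
               "non-empty")
})
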