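test_that("brain phantom satisfies its stated susceptibility geography", {
  spec <- phantom_spec("brain", grid = voxel_grid(c(32, 32, 32)), seed = 7)
  ph <- make_brain_phantom(spec)
  hm <- ph$head_mask$values > 0.5
  bm <- ph$brain_mask$values > 0.5
  # every exterior voxel is air at 9 ppm
  expect_true(all(ph$chi_true$values[!hm] == 9))
  # every in-brain voxel lies in the tissue range (no hemorrhage by default)
  expect_true(all(ph$chi_true$values[bm] >= -0.1 - 1e-12))
  expect_true(all(ph$chi_true$values[bm] <= 0.3 + 1e-12))
  # R2* floor inside the brain, large apparent R2* in air
  expect_true(all(ph$r2star_true$values[bm] >= 10 - 1e-12))
  expect_true(all(ph$r2star_true$values[!hm] == spec$air_r2star_per_s))
  # brain strictly inside head
  expect_true(all(hm[bm]))
  expect_gt(sum(hm), sum(bm))
})

test_that("brain phantom is a pure function of its spec", {
  spec <- phantom_spec("brain", grid = voxel_grid(c(32, 32, 32)), seed = 7)
  a <- make_brain_phantom(spec)
  b <- make_brain_phantom(spec)
  expect_identical(a$chi_true$values, b$chi_true$values)
  expect_identical(a$r2star_true$values, b$r2star_true$values)
  spec2 <- phantom_spec("brain", grid = voxel_grid(c(32, 32, 32)), seed = 8)
  c2 <- make_brain_phantom(spec2)
  expect_false(identical(a$chi_true$values, c2$chi_true$values))
  expect_error(phantom_spec("brain", grid = voxel_grid(c(16, 16, 16))),
               ">= 32")
})

test_that("hemorrhage sphere is honored and bounded by the brain", {
  spec <- phantom_spec("brain", grid = voxel_grid(c(48, 48, 48)), seed = 7,
                       hemorrhage_radius_mm = 3)
  ph <- make_brain_phantom(spec)
  expect_true(any(ph$chi_true$values == 1.0))
  hem <- ph$chi_true$values == 1.0
  expect_true(all(ph$brain_mask$values[hem] == 1))
  big <- phantom_spec("brain", grid = voxel_grid(c(48, 48, 48)), seed = 7,
                      hemorrhage_radius_mm = 20)
  expect_error(make_brain_phantom(big), "fit inside")
})

test_that("gadolinium phantom encodes the 0.33 ppm/mM relation exactly", {
  spec <- phantom_spec("gd_spheres", seed = 1,
                       gd_concentrations_mM = c(0, 0.5, 1, 2, 3, 4))
  ph <- make_gd_phantom(spec)
  tab <- roi_stats(ph$chi_true, ph$sphere_labels)
  expect_equal(nrow(tab), 6)
  expect_equal(tab$std, rep(0, 6))
  # c = 2 mM sphere carries exactly 0.66 ppm; c = 0 carries 0
  expect_equal(tab$mean[4], 0.66)
  expect_equal(tab$mean[1], 0)
  fit <- regression_slope(spec$gd_concentrations_mM, tab$mean)
  expect_equal(fit$slope, 0.33, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  # the external background source lies outside the phantom mask
  ext <- ph$chi_true$values == spec$background_ppm
  expect_true(any(ext))
  expect_true(all(ph$mask$values[ext] == 0))
  # overcrowding the ring of spheres raises
  expect_error(make_gd_phantom(
    phantom_spec("gd_spheres", gd_concentrations_mM = seq(0.2, 4, 0.2))),
    "overlap")
})

test_that("simulated GRE signal follows the closed-form forward model", {
  spec <- phantom_spec("brain", grid = voxel_grid(c(32, 32, 32)),
                       background_ppm = 0, seed = 2)
  ph <- make_brain_phantom(spec)
  sim <- simulate_gre(ph$chi_true, ph$r2star_true, ph$head_mask, spec)
  hm <- ph$head_mask$values > 0.5
  f_hz <- sim$field_ppm$values * 42.576e6 * 3 * 1e-6
  for (j in c(1, 4, 8)) {
    echo <- sim$gre$echoes[, , , j]
    te <- spec$te_s[j]
    expect_equal(Mod(echo)[hm], exp(-te * ph$r2star_true$values)[hm],
                 tolerance = 1e-12)
    # phase equals 2 pi f TE exactly (compare as complex units)
    expect_lt(max(Mod(exp(1i * 2 * pi * f_hz * te)[hm] -
                        echo[hm] / Mod(echo)[hm])), 1e-9)
    expect_true(all(Mod(echo)[!hm] == 0))
  }
  # noisy simulation is seeded: identical spec, identical noise
  specn <- phantom_spec("brain", grid = voxel_grid(c(32, 32, 32)),
                        background_ppm = 0, noise_snr = 50, seed = 2)
  s1 <- simulate_gre(ph$chi_true, ph$r2star_true, ph$head_mask, specn)
  s2 <- simulate_gre(ph$chi_true, ph$r2star_true, ph$head_mask, specn)
  expect_identical(s1$gre$echoes, s2$gre$echoes)
  expect_false(identical(s1$gre$echoes, sim$gre$echoes))
})

test_that("simulate_gre warns when echo spacing would wrap the phase", {
  spec <- phantom_spec("brain", grid = voxel_grid(c(32, 32, 32)), seed = 2)
  ph <- make_brain_phantom(spec)  # 9 ppm background: fields of several ppm
  expect_warning(simulate_gre(ph$chi_true, ph$r2star_true, ph$head_mask,
                              spec),
                 "unwrapping")
})

test_that("noiseless round trip: fits invert the forward simulation", {
  spec <- phantom_spec("brain", grid = voxel_grid(c(32, 32, 32)),
                       background_ppm = 0, seed = 2)
  ph <- make_brain_phantom(spec)
  sim <- simulate_gre(ph$chi_true, ph$r2star_true, ph$head_mask, spec)
  fit <- fit_total_field(sim$gre, ph$head_mask, spec$b0_tesla)
  hm <- ph$head_mask$values > 0.5
  expect_lt(sqrt(mean((fit$field_ppm$values[hm] -
                         sim$field_ppm$values[hm])^2)), 1e-6)
  expect_lt(sqrt(mean((fit$r2star$values[hm] -
                         ph$r2star_true$values[hm])^2)), 1e-6)
})

test_that("forward fields superpose and padding controls aliasing", {
  spec <- phantom_spec("brain", grid = voxel_grid(c(32, 32, 32)),
                       background_ppm = 0, seed = 3)
  ph <- make_brain_phantom(spec)
  g <- spec$grid
  bump <- array(0, g$dims); bump[10:14, 10:14, 10:14] <- 0.5
  fa <- forward_field(ph$chi_true)$values
  fb <- forward_field(scalar_volume(bump, g, "susceptibility_ppm"))$values
  fab <- forward_field(scalar_volume(ph$chi_true$values + bump, g,
                                     "susceptibility_ppm"))$values
  expect_lt(max(abs(fab - fa - fb)), 1e-10)
  # compact head <= half the FOV: padding changes exterior fields by < 1%
  # of the field scale (peak magnitude)
  f_pad <- forward_field(ph$chi_true, pad = TRUE)$values
  f_circ <- forward_field(ph$chi_true, pad = FALSE)$values
  ext <- ph$head_mask$values < 0.5
  rel <- sqrt(mean((f_pad - f_circ)[ext]^2)) / max(abs(f_pad))
  expect_lt(rel, 0.01)
})

test_that("shadow phantom injects exactly its smooth component", {
  spec <- small_shadow_spec(seed = 4)
  ph <- make_shadow_phantom(spec)
  expect_equal(ph$f_contaminated$values - ph$f_clean$values,
               ph$injected$values, tolerance = 1e-12)
  # spectral check: injected energy above the cutoff frequency is < 1%
  P <- Mod(stats::fft(ph$injected$values))^2
  g <- spec$grid
  kx <- qsmtfir:::fftfreq(g$dims[1], g$voxel_size_mm[1])
  k2 <- array(kx^2, g$dims) +
    array(rep(qsmtfir:::fftfreq(g$dims[2], g$voxel_size_mm[2])^2,
              each = g$dims[1]), g$dims) +
    array(rep(qsmtfir:::fftfreq(g$dims[3], g$voxel_size_mm[3])^2,
              each = g$dims[1] * g$dims[2]), g$dims)
  cutoff <- 0.05  # cycles/mm: wavelength 20 mm, far above the 1 mm kernel
  expect_lt(sum(P[k2 > cutoff^2]) / sum(P), 0.01)
  # zero amplitude degenerates to the clean brain phantom path
  spec0 <- small_shadow_spec(seed = 4, shadow_amplitude_ppm = 0)
  ph0 <- make_shadow_phantom(spec0)
  expect_identical(ph0$f_contaminated$values, ph0$f_clean$values)
  expect_identical(ph0$chi_true$values, ph$chi_true$values)
})
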