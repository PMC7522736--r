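# Synthetic data generation: a numerical brain phantom with an air-like
# 9 ppm background, a gadolinium sphere phantom with an external background
# source, a shadow-provoking contaminated-field scenario, and the forward
# multi-echo GRE signal simulator.  All generators are pure functions of
# their specification (including its seed).

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# voxel-center coordinates in mm, origin at the grid center
coords_mm <- function(grid) {
  d <- grid$dims
  vs <- grid$voxel_size_mm
  cx <- (seq_len(d[1]) - (d[1] + 1) / 2) * vs[1]
  cy <- (seq_len(d[2]) - (d[2] + 1) / 2) * vs[2]
  cz <- (seq_len(d[3]) - (d[3] + 1) / 2) * vs[3]
  list(X = array(cx, d),
       Y = array(rep(cy, each = d[1]), d),
       Z = array(rep(cz, each = d[1] * d[2]), d))
}

ellipsoid_mask <- function(co, center_mm, semi_mm) {
  ((co$X - center_mm[1]) / semi_mm[1])^2 +
    ((co$Y - center_mm[2]) / semi_mm[2])^2 +
    ((co$Z - center_mm[3]) / semi_mm[3])^2 <= 1
}

sphere_mask <- function(co, center_mm, radius_mm) {
  (co$X - center_mm[1])^2 + (co$Y - center_mm[2])^2 +
    (co$Z - center_mm[3])^2 <= radius_mm^2
}

#' Phantom specification
#'
#' Bundles the geometry and physical parameters of the synthetic scenarios.
#' Defaults encode the study conditions: air-like background of 9 ppm,
#' brain-tissue susceptibilities within \[-0.1, 0.3\] ppm, bone at -2 ppm,
#' a gadolinium susceptibility relation of 0.33 ppm/mM, B0 = 3 T.
#'
#' @param scenario one of `"brain"`, `"gd_spheres"`, `"shadow"`.
#' @param grid a [voxel_grid()]; defaults per scenario (64^3 at 1 mm for
#'   `brain`, 64 x 64 x 48 at 1 mm for `gd_spheres`, 32^3 at 2 mm for
#'   `shadow` — shadow artifacts are smooth, so a coarse grid suffices).
#' @param background_ppm exterior (air) susceptibility, ppm.
#' @param tissue_range_ppm range of brain-tissue susceptibilities, ppm.
#' @param hemorrhage_ppm hemorrhage susceptibility, ppm.
#' @param hemorrhage_radius_mm hemorrhage radius; 0 disables the hemorrhage
#'   (the default brain scenario models a healthy head).
#' @param gd_concentrations_mM gadolinium concentrations, one sphere each.
#' @param gd_slope_ppm_per_mM susceptibility per unit concentration.
#' @param noise_snr signal-to-noise ratio of the simulated GRE magnitude;
#'   `Inf` for noiseless.
#' @param te_s echo times, seconds.
#' @param b0_tesla field strength.
#' @param seed integer seed; generators are pure functions of the spec.
#' @param include_skull add a -2 ppm bone shell around the brain (off by
#'   default: the numerical-phantom scenario is defined by its air-like
#'   background; the bone shell is an optional extra).
#' @param skull_ppm,skull_r2star_per_s bone susceptibility and R2*.
#' @param r2star_floor_per_s,r2star_per_ppm brain R2* model: floor plus a
#'   linear term in the susceptibility deviation from the tissue baseline,
#'   so high-contrast regions carry high R2*.
#' @param gd_r2star_base_per_s,gd_r2star_per_mM agarose R2* and gadolinium
#'   relaxivity.
#' @param air_r2star_per_s apparent R2* assigned to signal-free air regions.
#'   Air carries no coherent signal, so its measured magnitude decays at the
#'   noise floor and the apparent R2* is very large; this is what makes the
#'   adaptive mask r nearly zero in air, leaving large background
#'   susceptibilities essentially unpenalized.
#' @param shadow_amplitude_ppm amplitude of the injected smooth spurious
#'   field in the shadow scenario.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(scenario = c("brain", "gd_spheres", "shadow"),
                         grid = NULL,
                         background_ppm = 9,
                         tissue_range_ppm = c(-0.1, 0.3),
                         hemorrhage_ppm = 1.0,
                         hemorrhage_radius_mm = 0,
                         gd_concentrations_mM = c(0.5, 1, 2, 3, 4),
                         gd_slope_ppm_per_mM = 0.33,
                         noise_snr = Inf,
                         te_s = seq(0.004, 0.032, by = 0.004),
                         b0_tesla = 3,
                         seed = 1L,
                         include_skull = FALSE,
                         skull_ppm = -2,
                         skull_r2star_per_s = 60,
                         r2star_floor_per_s = 10,
                         r2star_per_ppm = 100,
                         gd_r2star_base_per_s = 20,
                         gd_r2star_per_mM = 5,
                         air_r2star_per_s = 150,
                         shadow_amplitude_ppm = 0.05) {
  scenario <- match.arg(scenario)
  if (is.null(grid)) {
    grid <- switch(scenario,
                   brain = voxel_grid(c(64, 64, 64)),
                   gd_spheres = voxel_grid(c(64, 64, 48)),
                   shadow = voxel_grid(c(32, 32, 32), voxel_size_mm = c(2, 2, 2)))
  }
  stopifnot(inherits(grid, "voxel_grid"))
  if (scenario %in% c("brain", "shadow") && any(grid$dims < 32))
    stop("brain-based scenarios need grid dims >= 32")
  if (any(gd_concentrations_mM < 0)) stop("concentrations must be >= 0")
  if (!is.infinite(noise_snr) && noise_snr <= 0) stop("noise_snr must be > 0")
  structure(list(scenario = scenario, grid = grid,
                 background_ppm = background_ppm,
                 tissue_range_ppm = tissue_range_ppm,
                 hemorrhage_ppm = hemorrhage_ppm,
                 hemorrhage_radius_mm = hemorrhage_radius_mm,
                 gd_concentrations_mM = gd_concentrations_mM,
                 gd_slope_ppm_per_mM = gd_slope_ppm_per_mM,
                 noise_snr = noise_snr, te_s = te_s, b0_tesla = b0_tesla,
                 seed = as.integer(seed), include_skull = include_skull,
                 skull_ppm = skull_ppm,
                 skull_r2star_per_s = skull_r2star_per_s,
                 r2star_floor_per_s = r2star_floor_per_s,
                 r2star_per_ppm = r2star_per_ppm,
                 gd_r2star_base_per_s = gd_r2star_base_per_s,
                 gd_r2star_per_mM = gd_r2star_per_mM,
                 air_r2star_per_s = air_r2star_per_s,
                 shadow_amplitude_ppm = shadow_amplitude_ppm),
            class = "phantom_spec")
}

#' Numerical brain phantom with air background
#'
#' An ellipsoidal head (extent at most half the field of view per axis, to
#' keep padded forward fields alias-controlled) containing: a smooth
#' low-amplitude tissue baseline, 6-10 seeded spherical nuclei with
#' susceptibilities drawn within the tissue range, a near-zero ventricle,
#' an optional hemorrhage sphere, and an optional -2 ppm bone shell.  Every
#' voxel outside the head is set to the background susceptibility (9 ppm by
#' default, mimicking air).  The ground-truth R2* is the floor plus a linear
#' term in |chi - baseline| inside the head (bone fixed separately, air 0),
#' so regions of high susceptibility contrast carry high R2* — the premise
#' behind the adaptive weight mask.  Fully deterministic given the spec.
#'
#' @param spec a [phantom_spec()] with `scenario = "brain"` (or `"shadow"`).
#' @return A list with `chi_true`, `r2star_true` ([scalar_volume()]s),
#'   `brain_mask`, `head_mask` (binary [scalar_volume()]s).
#' @export
make_brain_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!spec$scenario %in% c("brain", "shadow"))
    stop("spec$scenario must be 'brain' or 'shadow'")
  grid <- spec$grid
  d <- grid$dims
  vs <- grid$voxel_size_mm
  co <- coords_mm(grid)
  fov <- d * vs
  semi <- c(0.24, 0.25, 0.21) * fov          # head <= half FOV per axis
  shell <- 2 * max(vs)                       # skull shell thickness, mm
  head <- ellipsoid_mask(co, c(0, 0, 0), semi)
  # without a skull shell the tissue fills the whole head
  inner <- if (spec$include_skull)
    ellipsoid_mask(co, c(0, 0, 0), semi - shell) else head
  brain <- ellipsoid_mask(co, c(0, 0, 0), semi - 1.5 * shell)

  with_seed(spec$seed, {
    baseline <- array(0, d)
    for (i in 1:3) {
      ctr <- stats::runif(3, -0.3, 0.3) * semi
      sg <- stats::runif(1, 0.15, 0.3) * min(fov)
      amp <- stats::runif(1, -0.02, 0.02)
      baseline <- baseline + amp * exp(-((co$X - ctr[1])^2 + (co$Y - ctr[2])^2 +
                                           (co$Z - ctr[3])^2) / (2 * sg^2))
    }
    baseline <- pmin(pmax(baseline, -0.02), 0.02)
    chi <- baseline

    n_nuc <- sample(6:10, 1)
    lo <- spec$tissue_range_ppm[1]
    hi <- spec$tissue_range_ppm[2]
    for (i in seq_len(n_nuc)) {
      # nucleus must fit inside the brain ellipsoid whatever the grid size
      rad <- min(stats::runif(1, 2, 4) * max(vs),
                 0.5 * min(semi - 1.5 * shell))
      tries <- 0L
      repeat {
        ctr <- stats::runif(3, -0.6, 0.6) * pmax(semi - 1.5 * shell - rad, 0)
        if (all(brain[sphere_mask(co, ctr, rad)])) break
        tries <- tries + 1L
        if (tries %% 25L == 0L) rad <- 0.8 * rad
      }
      chi[sphere_mask(co, ctr, rad)] <- stats::runif(1, lo, hi)
    }

    vent <- ellipsoid_mask(co, c(0, 0, 0), c(0.1, 0.18, 0.1) * fov / 2)
    chi[vent] <- 0

    if (spec$hemorrhage_radius_mm > 0) {
      hctr <- c(0.35 * semi[1], 0.15 * semi[2], -0.2 * semi[3])
      hem <- sphere_mask(co, hctr, spec$hemorrhage_radius_mm)
      if (any(hem & !brain))
        stop("hemorrhage sphere does not fit inside the brain mask")
      chi[hem] <- spec$hemorrhage_ppm
    }

    r2s <- spec$r2star_floor_per_s + spec$r2star_per_ppm * abs(chi - baseline)
    chi[!inner] <- if (spec$include_skull) spec$skull_ppm else spec$background_ppm
    chi[!head] <- spec$background_ppm
    r2s[!inner] <- if (spec$include_skull) spec$skull_r2star_per_s else
      spec$air_r2star_per_s
    r2s[!head] <- spec$air_r2star_per_s
  })

  list(chi_true = scalar_volume(chi, grid, "susceptibility_ppm"),
       r2star_true = scalar_volume(r2s, grid, "r2star_per_s"),
       brain_mask = scalar_volume(array(as.numeric(brain), d), grid, "mask"),
       head_mask = scalar_volume(array(as.numeric(head), d), grid, "mask"))
}

#' Simulated gadolinium sphere phantom
#'
#' A cylindrical agarose body of susceptibility 0 containing one sphere per
#' gadolinium concentration, with `chi = slope * concentration`
#' (0.33 ppm/mM by default).  An external high-susceptibility ellipsoid
#' placed above the cylinder, outside the mask, injects a strong background
#' field so that total-field reconstruction is actually exercised.  Sphere
#' R2* scales with concentration (relaxivity `gd_r2star_per_mM`), so the
#' adaptive mask sees the spheres.
#'
#' @param spec a [phantom_spec()] with `scenario = "gd_spheres"` and at
#'   least 3 concentrations.
#' @return A list with `chi_true`, `r2star_true`, `mask` (the cylinder),
#'   and `sphere_labels` (integer label volume, label i = i-th
#'   concentration, 0 elsewhere).
#' @export
make_gd_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$scenario != "gd_spheres") stop("spec$scenario must be 'gd_spheres'")
  conc <- spec$gd_concentrations_mM
  if (length(conc) < 3) stop("need at least 3 concentrations")
  grid <- spec$grid
  d <- grid$dims
  co <- coords_mm(grid)
  fov <- d * grid$voxel_size_mm

  cyl_r <- 0.34 * min(fov[1:2])
  cyl_hz <- 0.30 * fov[3]
  cyl <- (co$X^2 + co$Y^2 <= cyl_r^2) & (abs(co$Z) <= cyl_hz)

  n <- length(conc)
  ring_r <- 0.6 * cyl_r
  sph_r <- min(2.5 * max(grid$voxel_size_mm), 0.18 * cyl_r)
  ang <- 2 * pi * (seq_len(n) - 1) / n
  centers <- cbind(ring_r * cos(ang), ring_r * sin(ang), 0)
  # overlap guard: ring chord must exceed the sphere diameter
  if (n > 1 && 2 * ring_r * sin(pi / n) <= 2 * sph_r)
    stop("gadolinium spheres would overlap; reduce their number or radius")

  chi <- array(0, d)
  labels <- array(0L, d)
  r2s <- array(spec$air_r2star_per_s, d)
  r2s[cyl] <- spec$gd_r2star_base_per_s
  for (i in seq_len(n)) {
    sph <- sphere_mask(co, centers[i, ], sph_r)
    if (any(sph & !cyl)) stop("gadolinium sphere extends outside the cylinder")
    chi[sph] <- spec$gd_slope_ppm_per_mM * conc[i]
    r2s[sph] <- spec$gd_r2star_base_per_s + spec$gd_r2star_per_mM * conc[i]
    labels[sph] <- i
  }

  ext_ctr <- c(0, 0, cyl_hz + 0.12 * fov[3])
  ext <- ellipsoid_mask(co, ext_ctr, c(0.28 * fov[1], 0.28 * fov[2],
                                       0.06 * fov[3]))
  ext <- ext & !cyl
  chi[ext] <- spec$background_ppm

  list(chi_true = scalar_volume(chi, grid, "susceptibility_ppm"),
       r2star_true = scalar_volume(r2s, grid, "r2star_per_s"),
       mask = scalar_volume(array(as.numeric(cyl), d), grid, "mask"),
       sphere_labels = scalar_volume(array(as.numeric(labels), d), grid,
                                     "generic"))
}

#' Forward dipole field of a susceptibility map
#'
#' Convenience wrapper: zero-padded dipole convolution (the simulator's
#' regime, where aliasing of strong background sources matters).
#'
#' @param chi a susceptibility [scalar_volume()] (ppm).
#' @param pad zero-pad to double size (default `TRUE`).
#' @return The field as a [scalar_volume()] of kind `"field_ppm"`.
#' @export
forward_field <- function(chi, pad = TRUE) {
  apply_kspace(dipole_kernel(chi$grid), chi, pad = pad)
}

#' Simulate a multi-echo GRE acquisition
#'
#' Forward signal model `S_j = M0 exp(-TE_j R2*) exp(i 2 pi f_Hz TE_j)` with
#' `f_Hz = field_ppm * 42.576e6 * b0_tesla * 1e-6`, `M0 = 1` inside the
#' mask and 0 outside.  The field is the zero-padded dipole convolution of
#' the ground truth.  Complex Gaussian noise is added at `spec$noise_snr`
#' (per-channel standard deviation `M0 / (snr * sqrt(2))`), seeded by the
#' spec.  A warning is issued if any in-mask inter-echo phase increment
#' reaches pi (temporal unwrapping would no longer be exact).
#'
#' @param chi_true,r2star_true,mask [scalar_volume()]s on one grid.
#' @param spec a [phantom_spec()] supplying `te_s`, `b0_tesla`,
#'   `noise_snr`, `seed`.
#' @return A list with `gre` (a [multi_echo_gre()]) and `field_ppm` (the
#'   simulated total field, a [scalar_volume()]).
#' @export
simulate_gre <- function(chi_true, r2star_true, mask, spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  check_same_grid(chi_true, r2star_true)
  check_same_grid(chi_true, mask)
  if (!is.infinite(spec$noise_snr) && spec$noise_snr <= 0)
    stop("noise_snr must be > 0")
  grid <- chi_true$grid
  d <- grid$dims
  field <- forward_field(chi_true, pad = TRUE)
  f_hz <- field$values * GYROMAGNETIC_HZ_PER_T * spec$b0_tesla * 1e-6
  inmask <- mask$values > 0.5
  max_step <- max(abs(2 * pi * f_hz[inmask] * max(diff(spec$te_s))))
  if (max_step >= pi)
    warning(sprintf("inter-echo phase increments reach %.2f rad (>= pi): temporal unwrapping will not be exact", max_step))
  m0 <- array(as.numeric(inmask), d)
  ne <- length(spec$te_s)
  echoes <- array(complex(real = 0), c(d, ne))
  for (j in seq_len(ne)) {
    te <- spec$te_s[j]
    echoes[, , , j] <- m0 * exp(-te * r2star_true$values) *
      exp(1i * 2 * pi * f_hz * te)
  }
  if (is.finite(spec$noise_snr)) {
    sdv <- m0 / (spec$noise_snr * sqrt(2))
    with_seed(spec$seed, {
      for (j in seq_len(ne)) {
        echoes[, , , j] <- echoes[, , , j] +
          complex(real = stats::rnorm(prod(d), 0, 1),
                  imaginary = stats::rnorm(prod(d), 0, 1)) * sdv
      }
    })
  }
  list(gre = multi_echo_gre(echoes, spec$te_s, grid), field_ppm = field)
}

#' Shadow-provoking phantom
#'
#' The brain phantom plus an additive smooth spurious field component — a
#' broad Gaussian bowl whose spatial scale far exceeds the regularizer's SMV
#' radius — emulating residual background-field / digitization error, the
#' failure mode that produces shadow artifacts.  Returns both the clean and
#' the contaminated total field.
#'
#' @param spec a [phantom_spec()] with `scenario = "shadow"`.
#' @return A list with the brain-phantom outputs plus `f_clean`,
#'   `f_contaminated` and `injected` (the spurious component,
#'   [scalar_volume()]s of kind `"field_ppm"`).
#' @export
make_shadow_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$scenario != "shadow") stop("spec$scenario must be 'shadow'")
  ph <- make_brain_phantom(spec)
  grid <- spec$grid
  co <- coords_mm(grid)
  fov <- grid$dims * grid$voxel_size_mm
  sg <- min(fov) / 6
  ctr <- c(0.1, -0.08, 0.05) * fov
  bowl <- spec$shadow_amplitude_ppm *
    exp(-((co$X - ctr[1])^2 + (co$Y - ctr[2])^2 + (co$Z - ctr[3])^2) /
          (2 * sg^2))
  injected <- scalar_volume(bowl, grid, "field_ppm")
  f_clean <- forward_field(ph$chi_true, pad = TRUE)
  f_cont <- scalar_volume(f_clean$values + bowl, grid, "field_ppm")
  c(ph, list(f_clean = f_clean, f_contaminated = f_cont, injected = injected))
}
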