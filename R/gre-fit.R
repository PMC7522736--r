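# Estimation of the solver inputs from multi-echo gradient-echo data:
# R2* by magnitude-weighted log-linear decay fitting, the total field by
# temporally unwrapped weighted phase-slope fitting, and the SNR weight
# from the late-echo magnitude.

GYROMAGNETIC_HZ_PER_T <- 42.576e6  # proton gyromagnetic ratio / 2pi

#' Fit an R2* map from multi-echo magnitude decay
#'
#' Per-voxel mono-exponential decay rate from `|S_j|` versus echo time via
#' log-linear least squares weighted by the squared magnitude (near maximum
#' likelihood for Gaussian noise at moderate SNR, and available in closed
#' form).  Negative estimates are clipped to 0; voxels outside the mask are
#' set to 0.  The estimate is invariant to global magnitude scaling.
#'
#' @param data a [multi_echo_gre()].
#' @param mask a [scalar_volume()] of kind `"mask"` on the same grid.
#' @return A [scalar_volume()] of kind `"r2star_per_s"`.
#' @export
fit_r2star <- function(data, mask) {
  stopifnot(inherits(data, "multi_echo_gre"), inherits(mask, "scalar_volume"))
  check_same_grid(data$grid, mask$grid)
  d <- data$grid$dims
  ne <- length(data$te_s)
  nvox <- prod(d)
  mag <- matrix(Mod(data$echoes), nvox, ne)
  inmask <- as.vector(mask$values) > 0.5
  dead <- inmask & (rowSums(mag > 0) < 2L)
  if (any(dead))
    warning(sum(dead), " in-mask voxel(s) with <2 nonzero echoes excluded from R2* fit")
  fit <- inmask & !dead
  r2s <- numeric(nvox)
  if (any(fit)) {
    m <- mag[fit, , drop = FALSE]
    w <- m^2
    # guard zero-magnitude echoes within otherwise fittable voxels
    logm <- log(pmax(m, .Machine$double.xmin))
    w[m <= 0] <- 0
    te <- data$te_s
    sw <- rowSums(w)
    swt <- w %*% te
    swt2 <- w %*% te^2
    swy <- rowSums(w * logm)
    swty <- (w * logm) %*% te
    denom <- sw * swt2 - swt^2
    slope <- (sw * swty - swt * swy) / denom
    slope[!is.finite(slope)] <- 0
    r2s[fit] <- pmax(-slope, 0)
  }
  scalar_volume(array(r2s, d), data$grid, "r2star_per_s")
}

# wrap phase into (-pi, pi]
wrap_phase <- function(p) {
  w <- (p + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

#' Noise weight from signal magnitude
#'
#' SNR weighting for the data-fidelity term: proportional to the magnitude
#' inside the mask, 0 outside, rescaled to unit mean over the mask.  The
#' normalization makes the weight invariant to global magnitude scaling.
#'
#' @param magnitude a [scalar_volume()] with non-negative values.
#' @param mask a [scalar_volume()] of kind `"mask"`.
#' @return A [scalar_volume()] of kind `"weight"` with in-mask mean 1.
#' @export
noise_weight <- function(magnitude, mask) {
  stopifnot(inherits(magnitude, "scalar_volume"),
            inherits(mask, "scalar_volume"))
  check_same_grid(magnitude, mask)
  if (any(magnitude$values < 0)) stop("magnitude must be non-negative")
  inmask <- mask$values > 0.5
  if (!any(inmask)) stop("mask is empty")
  w <- magnitude$values * inmask
  mu <- mean(w[inmask])
  if (mu <= 0) stop("magnitude is zero everywhere inside the mask")
  scalar_volume(w / mu, magnitude$grid, "weight")
}

#' Fit the total field and companion maps from multi-echo GRE data
#'
#' Per-voxel phase evolution is temporally unwrapped (successive-echo phase
#' differences wrapped into `(-pi, pi]`, then cumulated), and the field is
#' the slope of a magnitude^2-weighted linear fit of unwrapped phase versus
#' echo time (intercept free, absorbing coil phase).  The slope in rad/s is
#' converted to ppm by dividing by `2 pi * 42.576e6 * b0_tesla * 1e-6`.
#' Temporal unwrapping is exact whenever every inter-echo phase increment is
#' below pi in magnitude; synthetic echo times must be chosen wrap-safe.
#' Spatial unwrapping is not performed.
#'
#' @param data a [multi_echo_gre()] with >= 2 echoes (>= 3 recommended).
#' @param mask a [scalar_volume()] of kind `"mask"`.
#' @param b0_tesla main field strength in tesla, > 0.
#' @return A list of class `fit_result` with elements `field_ppm`,
#'   `r2star`, `m0`, `weight` (all [scalar_volume()]s).  The weight is the
#'   last-echo magnitude normalized to unit mean over the mask.
#' @export
fit_total_field <- function(data, mask, b0_tesla) {
  stopifnot(inherits(data, "multi_echo_gre"), inherits(mask, "scalar_volume"))
  check_same_grid(data$grid, mask$grid)
  if (length(data$te_s) < 2L) stop("need at least 2 echoes")
  if (!is.numeric(b0_tesla) || b0_tesla <= 0) stop("b0_tesla must be > 0")
  d <- data$grid$dims
  ne <- length(data$te_s)
  nvox <- prod(d)
  ph <- matrix(Arg(data$echoes), nvox, ne)
  mag <- matrix(Mod(data$echoes), nvox, ne)
  # temporal unwrap: cumulate wrapped successive differences onto echo 1
  un <- ph
  dph <- wrap_phase(ph[, -1, drop = FALSE] - ph[, -ne, drop = FALSE])
  for (j in 2:ne) un[, j] <- un[, j - 1] + dph[, j - 1]
  # weighted LS slope of phase vs TE, weights = magnitude^2
  w <- mag^2
  te <- data$te_s
  sw <- rowSums(w)
  swt <- w %*% te
  swt2 <- w %*% te^2
  swy <- rowSums(w * un)
  swty <- (w * un) %*% te
  denom <- sw * swt2 - swt^2
  slope <- (sw * swty - swt * swy) / denom  # rad / s
  slope[!is.finite(slope)] <- 0
  inmask <- as.vector(mask$values) > 0.5
  slope[!inmask] <- 0
  field_ppm <- slope / (2 * pi * GYROMAGNETIC_HZ_PER_T * b0_tesla * 1e-6)
  # M0 from the magnitude fit intercept
  logm <- log(pmax(mag, .Machine$double.xmin))
  wm <- w
  wm[mag <= 0] <- 0
  swm <- rowSums(wm); swtm <- wm %*% te; swt2m <- wm %*% te^2
  swym <- rowSums(wm * logm); swtym <- (wm * logm) %*% te
  denm <- swm * swt2m - swtm^2
  icpt <- (swt2m * swym - swtm * swtym) / denm
  icpt[!is.finite(icpt)] <- 0
  m0 <- exp(icpt) * inmask
  last_mag <- scalar_volume(array(mag[, ne], d), data$grid, "generic")
  structure(list(
    field_ppm = scalar_volume(array(field_ppm, d), data$grid, "field_ppm"),
    r2star = fit_r2star(data, mask),
    m0 = scalar_volume(array(m0, d), data$grid, "generic"),
    weight = noise_weight(last_mag, mask)
  ), class = "fit_result")
}
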