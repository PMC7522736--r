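# Linear operators of the dipole-inversion objective: the k-space dipole
# kernel, spherical mean value (SMV) filtering, and the forward-difference
# gradient / divergence adjoint pair.  All k-space operators are real,
# symmetric frequency multipliers, hence self-adjoint and mutually commuting.

fftfreq <- function(n, d = 1) {
  # cycles per unit length, in FFT ordering
  k <- c(0:(ceiling(n / 2) - 1), -(floor(n / 2)):-1)
  k / (n * d)
}

fftn <- function(x) stats::fft(x)
ifftn_re <- function(X) Re(stats::fft(X, inverse = TRUE)) / length(X)

# circular shift: result[i] = a[i - s] with periodic wrap, along one axis
shift_arr <- function(a, axis, s) {
  n <- dim(a)[axis]
  s <- ((s %% n) + n) %% n
  if (s == 0) return(a)
  idx <- c((n - s + 1):n, 1:(n - s))
  switch(axis,
         a[idx, , , drop = FALSE],
         a[, idx, , drop = FALSE],
         a[, , idx, drop = FALSE])
}

new_kspace_kernel <- function(values, grid, kernel_kind,
                              params = list()) {
  structure(list(grid = grid, values = values, kernel_kind = kernel_kind,
                 params = params),
            class = "kspace_kernel")
}

#' @export
print.kspace_kernel <- function(x, ...) {
  cat(sprintf("<kspace_kernel [%s] %d x %d x %d>\n", x$kernel_kind,
              x$grid$dims[1], x$grid$dims[2], x$grid$dims[3]))
  invisible(x)
}

#' Unit dipole kernel in k-space
#'
#' Frequency response of the unit magnetic dipole along the grid's B0
#' direction, `D(k) = 1/3 - (k . b0)^2 / |k|^2`, evaluated on the discrete
#' frequency lattice implied by the grid dimensions and voxel size.  The
#' zero-frequency value is set to 0: the mean susceptibility is unobservable
#' from internal field data, so reconstructions are mean-free up to
#' regularization.  Values lie in [-2/3, 1/3] and vanish on the magic-angle
#' cone `3 (k . b0)^2 = |k|^2`.
#'
#' @param grid a [voxel_grid()].
#' @return A `kspace_kernel` with `kernel_kind = "dipole"`.
#' @export
dipole_kernel <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  kx <- fftfreq(grid$dims[1], grid$voxel_size_mm[1])
  ky <- fftfreq(grid$dims[2], grid$voxel_size_mm[2])
  kz <- fftfreq(grid$dims[3], grid$voxel_size_mm[3])
  b0 <- grid$b0_dir
  KX <- array(kx, grid$dims)
  KY <- array(rep(ky, each = grid$dims[1]), grid$dims)
  KZ <- array(rep(kz, each = grid$dims[1] * grid$dims[2]), grid$dims)
  k2 <- KX^2 + KY^2 + KZ^2
  kb <- KX * b0[1] + KY * b0[2] + KZ * b0[3]
  D <- 1 / 3 - kb^2 / k2
  D[1, 1, 1] <- 0  # k = 0: unobservable mean
  new_kspace_kernel(D, grid, "dipole")
}

#' Spherical mean value (SMV) kernel in k-space
#'
#' Frequency response of normalized averaging over all voxels whose centers
#' lie within `radius_mm` of the target voxel.  The sphere is built by
#' voxel-center membership (no antialiased shells), so on a 1 mm isotropic
#' grid a 1 mm radius yields the 7-voxel kernel (center plus 6-neighborhood,
#' each weighted 1/7).  The DC gain is exactly 1.  A radius smaller than the
#' smallest voxel dimension yields the identity operator.
#'
#' @param grid a [voxel_grid()].
#' @param radius_mm sphere radius in mm, >= 0.
#' @param complement if `TRUE`, return `I - SMV` (`kernel_kind
#'   "smv_complement"`), the high-pass residual filter used by SMV-filtered
#'   local-field inversion.
#' @return A `kspace_kernel`.
#' @export
smv_kernel <- function(grid, radius_mm, complement = FALSE) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (radius_mm < 0) stop("radius_mm must be >= 0")
  d <- grid$dims
  if (radius_mm < min(grid$voxel_size_mm)) {
    S <- array(1, d)  # sub-voxel radius: identity
  } else {
    vs <- grid$voxel_size_mm
    noff <- floor(radius_mm / vs)
    ox <- -noff[1]:noff[1]; oy <- -noff[2]:noff[2]; oz <- -noff[3]:noff[3]
    sphere <- array(0, d)
    cnt <- 0L
    for (dz in oz) for (dy in oy) for (dx in ox) {
      if ((dx * vs[1])^2 + (dy * vs[2])^2 + (dz * vs[3])^2 <= radius_mm^2) {
        ix <- ((dx %% d[1]) + d[1]) %% d[1] + 1L
        iy <- ((dy %% d[2]) + d[2]) %% d[2] + 1L
        iz <- ((dz %% d[3]) + d[3]) %% d[3] + 1L
        sphere[ix, iy, iz] <- sphere[ix, iy, iz] + 1
        cnt <- cnt + 1L
      }
    }
    sphere <- sphere / cnt
    S <- Re(fftn(sphere))
    S[1, 1, 1] <- 1  # exact unit DC gain
  }
  if (complement) {
    new_kspace_kernel(1 - S, grid, "smv_complement",
                      params = list(radius_mm = radius_mm))
  } else {
    new_kspace_kernel(S, grid, "smv", params = list(radius_mm = radius_mm))
  }
}

rebuild_kernel <- function(kernel, grid) {
  switch(kernel$kernel_kind,
         dipole = dipole_kernel(grid),
         smv = smv_kernel(grid, kernel$params$radius_mm),
         smv_complement = smv_kernel(grid, kernel$params$radius_mm,
                                     complement = TRUE),
         stop("cannot rebuild kernel of kind ", kernel$kernel_kind))
}

#' Apply a k-space kernel to a volume
#'
#' Circular (periodic) convolution via the frequency domain.  By default no
#' padding is used (the solver's regime, where speed matters and the model
#' is periodic by construction).  With `pad = TRUE` the volume is
#' zero-padded to double size per axis, the kernel is rebuilt on the padded
#' grid, and the result is cropped back — the simulator's regime, where
#' aliasing of strong background sources (e.g. 9 ppm air) matters.
#'
#' @param kernel a `kspace_kernel`.
#' @param vol a [scalar_volume()] on the same grid.
#' @param pad zero-pad to double size before convolving (default `FALSE`).
#' @return A [scalar_volume()]; kind `"field_ppm"` when the kernel is the
#'   dipole, otherwise the input kind.
#' @export
apply_kspace <- function(kernel, vol, pad = FALSE) {
  stopifnot(inherits(kernel, "kspace_kernel"), inherits(vol, "scalar_volume"))
  check_same_grid(kernel$grid, vol$grid)
  out_kind <- if (kernel$kernel_kind == "dipole") "field_ppm" else
    if (vol$kind %in% c("mask", "weight")) "generic" else vol$kind
  if (!pad) {
    res <- ifftn_re(kernel$values * fftn(vol$values))
    return(scalar_volume(res, vol$grid, out_kind))
  }
  d <- vol$grid$dims
  dp <- 2L * d
  gpad <- voxel_grid(dp, vol$grid$voxel_size_mm, vol$grid$b0_dir)
  kpad <- rebuild_kernel(kernel, gpad)
  big <- array(0, dp)
  big[1:d[1], 1:d[2], 1:d[3]] <- vol$values
  res <- ifftn_re(kpad$values * fftn(big))[1:d[1], 1:d[2], 1:d[3]]
  scalar_volume(array(res, d), vol$grid, out_kind)
}

#' Three-component vector volume (per-axis forward differences)
#'
#' @param components list of three 3D arrays (x, y, z components).
#' @param grid a [voxel_grid()].
#' @return An object of class `vector_volume`.
#' @export
vector_volume <- function(components, grid) {
  stopifnot(inherits(grid, "voxel_grid"), length(components) == 3L)
  for (comp in components)
    if (!all(dim(comp) == grid$dims)) stop("component dims must equal grid dims")
  structure(list(grid = grid, components = components), class = "vector_volume")
}

#' Forward-difference gradient
#'
#' Per-axis forward finite differences with periodic wrap (units: value per
#' voxel).  The periodic convention makes [divergence()] the exact negative
#' adjoint.
#'
#' @param vol a [scalar_volume()].
#' @return A [vector_volume()].
#' @export
gradient <- function(vol) {
  stopifnot(inherits(vol, "scalar_volume"))
  v <- vol$values
  comps <- lapply(1:3, function(ax) shift_arr(v, ax, -1L) - v)
  vector_volume(comps, vol$grid)
}

#' Divergence (negative adjoint of [gradient()])
#'
#' Backward differences with periodic wrap, summed over axes, so that
#' `<gradient(x), y> = <x, -divergence(y)>` holds exactly.
#'
#' @param v a [vector_volume()].
#' @return A [scalar_volume()] of kind `"generic"`.
#' @export
divergence <- function(v) {
  stopifnot(inherits(v, "vector_volume"))
  out <- array(0, v$grid$dims)
  for (ax in 1:3) {
    comp <- v$components[[ax]]
    out <- out + (comp - shift_arr(comp, ax, 1L))
  }
  scalar_volume(out, v$grid, "generic")
}

# Internal fast paths on raw arrays (used by the solver's inner loop).
grad_arrays <- function(v) {
  list(shift_arr(v, 1L, -1L) - v,
       shift_arr(v, 2L, -1L) - v,
       shift_arr(v, 3L, -1L) - v)
}

div_arrays <- function(comps) {
  (comps[[1]] - shift_arr(comps[[1]], 1L, 1L)) +
    (comps[[2]] - shift_arr(comps[[2]], 2L, 1L)) +
    (comps[[3]] - shift_arr(comps[[3]], 3L, 1L))
}
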