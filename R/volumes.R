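#' Voxel grid geometry
#'
#' A `voxel_grid` describes the geometry shared by all volumes in a
#' reconstruction: array dimensions, voxel size in millimetres, and the unit
#' direction of the main magnetic field B0.  Arrays are stored in (x, y, z)
#' order with x fastest, matching R's native column-major layout; no
#' reorientation (e.g. to RAS) is ever attempted.
#'
#' @param dims integer vector of length 3, all >= 4.
#' @param voxel_size_mm positive numeric vector of length 3 (mm per voxel).
#' @param b0_dir numeric length-3 unit vector, direction of B0.
#'   Defaults to `c(0, 0, 1)`.
#' @return An object of class `voxel_grid`.
#' @examples
#' g <- voxel_grid(c(32, 32, 32))
#' g$voxel_size_mm
#' @export
voxel_grid <- function(dims, voxel_size_mm = c(1, 1, 1), b0_dir = c(0, 0, 1)) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(!is.finite(dims)) || any(dims < 4L))
    stop("dims must be three integers, each >= 4")
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3L)
  if (length(voxel_size_mm) != 3L || any(!is.finite(voxel_size_mm)) ||
      any(voxel_size_mm <= 0))
    stop("voxel_size_mm must be three positive numbers")
  b0_dir <- as.numeric(b0_dir)
  if (length(b0_dir) != 3L || any(!is.finite(b0_dir)))
    stop("b0_dir must be a numeric 3-vector")
  nrm <- sqrt(sum(b0_dir^2))
  if (abs(nrm - 1) > 1e-9) {
    if (nrm == 0) stop("b0_dir must be non-zero")
    b0_dir <- b0_dir / nrm
  }
  structure(list(dims = dims, voxel_size_mm = voxel_size_mm, b0_dir = b0_dir),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid %d x %d x %d, voxel %.3g x %.3g x %.3g mm, b0 = (%.3g, %.3g, %.3g)>\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$voxel_size_mm[1], x$voxel_size_mm[2], x$voxel_size_mm[3],
              x$b0_dir[1], x$b0_dir[2], x$b0_dir[3]))
  invisible(x)
}

#' Test two grids for equality
#'
#' Grid equality (dims, voxel size, b0 direction) is required for every
#' binary operation between volumes; mismatches raise rather than broadcast.
#'
#' @param a,b `voxel_grid` objects.
#' @param tol numeric tolerance on voxel size and b0 direction.
#' @return Logical scalar.
#' @export
same_grid <- function(a, b, tol = 1e-9) {
  stopifnot(inherits(a, "voxel_grid"), inherits(b, "voxel_grid"))
  identical(a$dims, b$dims) &&
    all(abs(a$voxel_size_mm - b$voxel_size_mm) <= tol) &&
    all(abs(a$b0_dir - b$b0_dir) <= tol)
}

check_same_grid <- function(a, b) {
  ga <- if (inherits(a, "scalar_volume")) a$grid else a
  gb <- if (inherits(b, "scalar_volume")) b$grid else b
  if (!same_grid(ga, gb))
    stop("volumes are defined on different grids; refusing to broadcast")
  invisible(TRUE)
}

VOLUME_KINDS <- c("field_ppm", "susceptibility_ppm", "r2star_per_s",
                  "weight", "mask", "generic")

#' 3D scalar volume with a physical kind
#'
#' Wraps a real 3D array together with its [voxel_grid()] and a declared
#' physical kind.  Kind-specific invariants are enforced at construction:
#' masks must be binary (0/1), R2* maps and weights must be non-negative.
#'
#' @param values real 3D array whose dimensions equal `grid$dims`.
#' @param grid a [voxel_grid()].
#' @param kind one of `"field_ppm"`, `"susceptibility_ppm"`,
#'   `"r2star_per_s"`, `"weight"`, `"mask"`, `"generic"`.
#' @return An object of class `scalar_volume` with elements `grid`,
#'   `values`, `kind`.
#' @examples
#' g <- voxel_grid(c(8, 8, 8))
#' v <- scalar_volume(array(0.3, c(8, 8, 8)), g, "susceptibility_ppm")
#' @export
scalar_volume <- function(values, grid, kind = "generic") {
  stopifnot(inherits(grid, "voxel_grid"))
  kind <- match.arg(kind, VOLUME_KINDS)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("values must be a 3D array")
  if (!all(dim(values) == grid$dims))
    stop(sprintf("values have dims (%s) but grid expects (%s)",
                 paste(dim(values), collapse = ","),
                 paste(grid$dims, collapse = ",")))
  storage.mode(values) <- "double"
  if (any(!is.finite(values))) stop("values must be finite")
  validate_kind(values, kind)
  structure(list(grid = grid, values = values, kind = kind),
            class = "scalar_volume")
}

validate_kind <- function(values, kind, tol = 1e-6) {
  if (kind == "mask") {
    if (any(pmin(abs(values), abs(values - 1)) > tol))
      stop("mask volume contains values other than 0/1")
  } else if (kind == "r2star_per_s") {
    if (any(values < -tol)) stop("r2star volume contains negative values")
  } else if (kind == "weight") {
    if (any(values < -tol)) stop("weight volume contains negative values")
  }
  invisible(TRUE)
}

#' @export
print.scalar_volume <- function(x, ...) {
  rng <- range(x$values)
  cat(sprintf("<scalar_volume [%s] %d x %d x %d, range [%.4g, %.4g]>\n",
              x$kind, x$grid$dims[1], x$grid$dims[2], x$grid$dims[3],
              rng[1], rng[2]))
  invisible(x)
}

# Internal: rewrap an array as a volume on the same grid.
vol_like <- function(values, template, kind = template$kind) {
  scalar_volume(values, template$grid, kind)
}

#' Multi-echo gradient-echo container
#'
#' Holds per-echo complex 3D images on one grid together with their echo
#' times in seconds.
#'
#' @param echoes a 4D complex array (nx, ny, nz, n_echoes) or a list of
#'   complex 3D arrays.
#' @param te_s strictly increasing positive echo times, seconds; at least 2.
#' @param grid a [voxel_grid()].
#' @return An object of class `multi_echo_gre` with elements `grid`,
#'   `echoes` (4D complex array), `te_s`.
#' @export
multi_echo_gre <- function(echoes, te_s, grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (is.list(echoes)) {
    echoes <- array(unlist(lapply(echoes, as.complex)),
                    c(grid$dims, length(echoes)))
  }
  if (length(dim(echoes)) != 4L || !all(dim(echoes)[1:3] == grid$dims))
    stop("echoes must be a 4D array on the given grid")
  storage.mode(echoes) <- "complex"
  te_s <- as.numeric(te_s)
  if (length(te_s) < 2L || dim(echoes)[4] != length(te_s))
    stop("need >= 2 echoes with one echo time per echo image")
  if (any(te_s <= 0) || any(diff(te_s) <= 0))
    stop("te_s must be strictly increasing and positive")
  structure(list(grid = grid, echoes = echoes, te_s = te_s),
            class = "multi_echo_gre")
}

#' @export
print.multi_echo_gre <- function(x, ...) {
  cat(sprintf("<multi_echo_gre %d x %d x %d, %d echoes, TE %.3g-%.3g ms>\n",
              x$grid$dims[1], x$grid$dims[2], x$grid$dims[3],
              length(x$te_s), 1000 * min(x$te_s), 1000 * max(x$te_s)))
  invisible(x)
}
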