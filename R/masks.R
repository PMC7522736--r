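# Spatial weightings of the TFIR objective: the binary edge mask M_G that
# gates the total-variation penalty off at magnitude edges, and the
# continuous weight mask r = exp(-|tau * L R2*|) that adapts the L2 shadow
# penalty to local susceptibility contrast as seen by R2*.

#' Edge mask for the gradient (TV) penalty
#'
#' For each axis, the absolute forward difference of the magnitude image is
#' computed; the `edge_fraction` of in-mask voxels with the largest
#' differences are classified as edges and get `M_G = 0` (their gradients
#' are unpenalized), all other in-mask voxels get 1.  The threshold is the
#' per-axis `(1 - edge_fraction)` quantile of in-mask absolute differences;
#' all values tied with the threshold are included as edges, except that a
#' zero difference is never an edge (so a constant image yields an all-ones
#' mask).  The threshold is applied to every voxel of the grid, not only
#' in-mask voxels: one-sided differences that straddle the mask boundary
#' from outside (e.g. the air side of the head surface, always a strong
#' magnitude edge in practice) are classified by the same rule, so the TV
#' penalty never fights the structural susceptibility jump at the object
#' boundary.
#'
#' @param magnitude a [scalar_volume()] with non-negative values.
#' @param mask a [scalar_volume()] of kind `"mask"`.
#' @param edge_fraction fraction of in-mask voxels to mark as edges per axis,
#'   in `[0, 1]`; 0.1 preserves 10 percent of edge voxels.
#' @return A list of three [scalar_volume()]s of kind `"mask"` (x, y, z).
#' @export
edge_mask <- function(magnitude, mask, edge_fraction = 0.1) {
  stopifnot(inherits(magnitude, "scalar_volume"),
            inherits(mask, "scalar_volume"))
  check_same_grid(magnitude, mask)
  if (edge_fraction < 0 || edge_fraction > 1)
    stop("edge_fraction must be in [0, 1]")
  inmask <- mask$values > 0.5
  if (!any(inmask)) stop("mask is empty")
  g <- grad_arrays(magnitude$values)
  lapply(g, function(comp) {
    a <- abs(comp)
    thr <- stats::quantile(a[inmask], probs = 1 - edge_fraction,
                           names = FALSE, type = 7)
    mg <- array(1, dim(a))
    if (edge_fraction > 0) {
      edge <- (a >= thr) & (a > 0)
      mg[edge] <- 0
    }
    scalar_volume(mg, magnitude$grid, "mask")
  })
}

#' Adaptive shadow-suppression weight mask
#'
#' Computes `r = exp(-|tau * (L R2*)|)` pointwise, where `L` is a low-pass
#' filter (the SMV kernel of the regularizer).  Values lie in (0, 1]: r is
#' near 1 where the smoothed R2* is small (low expected susceptibility
#' contrast, heavy L2 penalty there suppresses shadows) and decays towards 0
#' where R2* is large (high contrast, penalty relaxed).  With `tau = 0` the
#' mask is identically 1 and the penalty degenerates to an unweighted
#' least-norm term.
#'
#' Outside an optional brain/head mask, r is set to its in-mask minimum
#' rather than 1, so that the L2 term does not dominate exterior voxels in
#' whole-head reconstructions where large background susceptibilities (air,
#' bone) must remain representable.
#'
#' @param r2star a [scalar_volume()] of kind `"r2star_per_s"`.
#' @param tau_s time constant in seconds, >= 0.
#' @param L a `kspace_kernel` with `kernel_kind = "smv"` (see
#'   [smv_kernel()]).
#' @param mask optional [scalar_volume()] of kind `"mask"`; if supplied, the
#'   exterior is set to the in-mask minimum of r.
#' @return A [scalar_volume()] of kind `"weight"` with values in (0, 1].
#' @export
weight_mask_r <- function(r2star, tau_s, L, mask = NULL) {
  stopifnot(inherits(r2star, "scalar_volume"), inherits(L, "kspace_kernel"))
  if (r2star$kind != "r2star_per_s") stop("r2star must have kind r2star_per_s")
  if (L$kernel_kind != "smv") stop("L must be an SMV kernel")
  if (tau_s < 0) stop("tau_s must be >= 0")
  check_same_grid(L$grid, r2star$grid)
  sm <- apply_kspace(L, r2star)
  r <- exp(-abs(tau_s * sm$values))
  if (!is.null(mask)) {
    check_same_grid(r2star, mask)
    inmask <- mask$values > 0.5
    if (!any(inmask)) stop("mask is empty")
    r[!inmask] <- min(r[inmask])
  }
  scalar_volume(r, r2star$grid, "weight")
}

#' Erode a binary mask by a spherical radius
#'
#' A voxel survives if the spherical neighborhood of `radius_mm` (by
#' voxel-center membership, as in [smv_kernel()]) lies entirely inside the
#' mask.  Used by the SMV-filtered local-field comparator, which cannot be
#' evaluated on the full mask, and by the shadow index.
#'
#' @param mask a [scalar_volume()] of kind `"mask"`.
#' @param radius_mm erosion radius in mm.
#' @return A [scalar_volume()] of kind `"mask"`.
#' @export
erode_mask <- function(mask, radius_mm) {
  stopifnot(inherits(mask, "scalar_volume"))
  if (radius_mm < min(mask$grid$voxel_size_mm)) return(mask)
  S <- smv_kernel(mask$grid, radius_mm)
  sm <- apply_kspace(S, scalar_volume(mask$values, mask$grid, "generic"))
  out <- array(0, mask$grid$dims)
  out[sm$values > 1 - 1e-9] <- 1
  scalar_volume(out, mask$grid, "mask")
}
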