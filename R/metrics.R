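# Quantitative evaluation: masked RMSE, per-ROI statistics, OLS regression
# slope, a shadow index (mean absolute low-pass residual, in ppb), and the
# binned susceptibility-versus-1/r correlation analysis.

#' Root-mean-square error over a mask
#'
#' @param chi,truth [scalar_volume()]s on one grid (ppm).
#' @param mask binary [scalar_volume()]; must be non-empty.
#' @return RMSE in ppm.
#' @export
rmse <- function(chi, truth, mask) {
  check_same_grid(chi, truth)
  check_same_grid(chi, mask)
  inmask <- mask$values > 0.5
  if (!any(inmask)) stop("mask is empty")
  sqrt(mean((chi$values[inmask] - truth$values[inmask])^2))
}

#' Per-ROI statistics
#'
#' Mean, standard deviation, coefficient of variation (std normalized to
#' the mean) and voxel count per label.  Label 0 is excluded; rows are
#' ordered by label id.
#'
#' @param chi a [scalar_volume()].
#' @param labels a [scalar_volume()] of non-negative integer labels.
#' @return A `data.frame` with columns `label`, `mean`, `std`,
#'   `std_over_mean`, `n`.
#' @export
roi_stats <- function(chi, labels) {
  check_same_grid(chi, labels)
  lab <- round(labels$values)
  if (any(lab < 0)) stop("labels must be non-negative integers")
  ids <- sort(unique(lab[lab > 0]))
  if (length(ids) == 0) stop("no nonzero labels")
  rows <- lapply(ids, function(id) {
    v <- chi$values[lab == id]
    m <- mean(v)
    s <- if (length(v) > 1) stats::sd(v) else 0
    data.frame(label = id, mean = m, std = s,
               std_over_mean = if (m != 0) s / m else NA_real_,
               n = length(v))
  })
  do.call(rbind, rows)
}

#' Ordinary least-squares regression
#'
#' @param x,y numeric vectors of equal length (>= 2 distinct x values).
#' @return A list with `slope`, `intercept`, `r_squared`.
#' @export
regression_slope <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 2) stop("need >= 2 paired values")
  if (length(unique(x)) < 2) stop("x is degenerate (all values equal)")
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  ssr <- sum(stats::residuals(fit)^2)
  sst <- sum((y - mean(y))^2)
  list(slope = unname(co[2]), intercept = unname(co[1]),
       r_squared = if (sst > 0) 1 - ssr / sst else 1)
}

#' Shadow index
#'
#' Quantifies smooth, low-spatial-frequency error bowls ("shadows"): the
#' ROI mean is removed from the map, the result is low-pass filtered with an
#' SMV kernel of the given radius, and the mean absolute filtered value over
#' the radius-eroded ROI is reported in ppb.  The index is zero for a
#' constant map, invariant to adding a global constant, insensitive to
#' high-frequency content (which the SMV averages away), and sensitive to
#' smooth bowls.
#'
#' @param chi a susceptibility [scalar_volume()] (ppm).
#' @param roi_mask binary [scalar_volume()]; must survive erosion by
#'   `radius_mm`.
#' @param radius_mm SMV / erosion radius (default 10 mm).
#' @return Shadow index in ppb.
#' @export
shadow_index <- function(chi, roi_mask, radius_mm = 10) {
  check_same_grid(chi, roi_mask)
  inroi <- roi_mask$values > 0.5
  if (!any(inroi)) stop("roi_mask is empty")
  er <- erode_mask(roi_mask, radius_mm)
  iner <- er$values > 0.5
  if (!any(iner)) stop("ROI vanishes after erosion by the SMV radius")
  centered <- scalar_volume(chi$values - mean(chi$values[inroi]),
                            chi$grid, "generic")
  S <- smv_kernel(chi$grid, radius_mm)
  low <- apply_kspace(S, centered)
  1000 * mean(abs(low$values[iner]))
}

#' Binned susceptibility versus 1/r correlation
#'
#' The rationale behind the adaptive weight mask: the pointwise inverse of
#' the weighting mask resembles the susceptibility map.  Susceptibility
#' values are binned (seven 0.05 ppm bins over \[0, 0.35\] ppm by default);
#' per bin the median of `1/r` is computed over the voxels whose
#' susceptibility falls in the bin, and an OLS regression of median(1/r)
#' against the bin-center susceptibility is reported.  Empty bins are
#' dropped with a warning.
#'
#' @param chi a susceptibility [scalar_volume()] (ppm).
#' @param r the weight [scalar_volume()] from [weight_mask_r()].
#' @param bin_width_ppm bin width (default 0.05 ppm).
#' @param range_ppm two-element range (default `c(0, 0.35)`).
#' @param mask optional binary [scalar_volume()] restricting the analysis.
#' @return A list with `bins` (a `data.frame` with `center_ppm`,
#'   `median_inv_r`, `n`), `slope`, `r_squared`.
#' @export
binned_inverse_r_correlation <- function(chi, r, bin_width_ppm = 0.05,
                                         range_ppm = c(0, 0.35),
                                         mask = NULL) {
  check_same_grid(chi, r)
  keep <- array(TRUE, chi$grid$dims)
  if (!is.null(mask)) {
    check_same_grid(chi, mask)
    keep <- mask$values > 0.5
  }
  edges <- seq(range_ppm[1], range_ppm[2], by = bin_width_ppm)
  nb <- length(edges) - 1
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  cv <- chi$values[keep]
  iv <- 1 / r$values[keep]
  rows <- lapply(seq_len(nb), function(i) {
    inbin <- cv >= edges[i] & (if (i == nb) cv <= edges[i + 1] else
      cv < edges[i + 1])
    data.frame(center_ppm = centers[i],
               median_inv_r = if (any(inbin)) stats::median(iv[inbin])
               else NA_real_,
               n = sum(inbin))
  })
  bins <- do.call(rbind, rows)
  if (any(bins$n == 0)) {
    warning(sum(bins$n == 0), " empty bin(s) dropped")
    bins <- bins[bins$n > 0, , drop = FALSE]
  }
  if (nrow(bins) < 2) stop("fewer than 2 occupied bins; cannot regress")
  fit <- regression_slope(bins$center_ppm, bins$median_inv_r)
  list(bins = bins, slope = fit$slope, r_squared = fit$r_squared)
}

#' Write an ROI table as comma-separated text
#'
#' Fixed column order for diffability.
#'
#' @param tab a `data.frame` from [roi_stats()] or [grid_search()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
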