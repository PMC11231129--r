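#' Maximum SUV within an ROI
#'
#' @param vol a [pet_volume()].
#' @param roi a [roi_mask()] congruent with `vol`.
#' @return SUVmax in g/mL.
#' @export
suv_max <- function(vol, roi) {
  check_roi(vol, roi)
  max(vol$data[roi$mask])
}

#' Mean SUV within an ROI
#'
#' @inheritParams suv_max
#' @return SUVmean in g/mL.
#' @export
suv_mean <- function(vol, roi) {
  check_roi(vol, roi)
  mean(vol$data[roi$mask])
}

#' Liver noise level (coefficient of variation, percent)
#'
#' Image noise is quantified as `100 * SD / mean` of the SUV values in a
#' homogeneous liver ROI. The sample (n-1) standard deviation is used; for
#' liver ROIs of thousands of voxels the distinction from the population
#' convention is negligible, but it is fixed here for reproducibility.
#'
#' @param vol a [pet_volume()].
#' @param liver liver [roi_mask()] with at least 2 voxels.
#' @return Noise level in percent.
#' @export
noise_level <- function(vol, liver) {
  check_roi(vol, liver)
  v <- vol$data[liver$mask]
  if (length(v) < 2L)
    stop("noise level needs >= 2 liver voxels", call. = FALSE)
  m <- mean(v)
  if (!is.finite(m) || m <= 0)
    stop("metric undefined: liver mean SUV is not positive", call. = FALSE)
  100 * stats::sd(v) / m
}

#' Absolute difference between two scalar measurements
#'
#' @param a,b finite scalars (e.g. two SUVmax values in g/mL, or two noise
#'   levels in percent — for noise the result is in percentage points).
#' @return `a - b`.
#' @export
delta_abs <- function(a, b) {
  stopifnot(is.finite(a), is.finite(b))
  a - b
}

#' Symmetric fractional difference (percent)
#'
#' `100 * (a - b) / ((a + b)/2)`. Symmetric in the sense that the
#' denominator treats both arguments alike, bounding the result to
#' [-200, 200] percent for non-negative inputs, and making the measure
#' antisymmetric: `delta_frac(a, b) == -delta_frac(b, a)`.
#'
#' @param a,b finite scalars with `a + b != 0` (the identical pair
#'   `a == b` is defined as 0, its continuous limit, even at 0).
#' @return Fractional difference in percent.
#' @export
delta_frac <- function(a, b) {
  stopifnot(is.finite(a), is.finite(b))
  if (a == b) return(0)
  if (a + b == 0)
    stop("metric undefined: a + b = 0", call. = FALSE)
  100 * (a - b) / ((a + b) / 2)
}

#' Focal-uptake-to-liver ratio (FLR)
#'
#' Lesion SUVmax divided by liver SUVmean: the target-to-background
#' contrast covariate of the evaluation.
#'
#' @param vol a [pet_volume()].
#' @param lesion lesion [roi_mask()].
#' @param liver liver [roi_mask()].
#' @return Dimensionless ratio.
#' @export
flr <- function(vol, lesion, liver) {
  lm <- suv_mean(vol, liver)
  if (lm <= 0)
    stop("metric undefined: liver mean SUV is not positive", call. = FALSE)
  suv_max(vol, lesion) / lm
}

check_roi <- function(vol, roi) {
  stopifnot(is_pet_volume(vol), inherits(roi, "roi_mask"))
  if (!identical(dim(roi$mask), dim(vol$data)))
    stop("ROI mask shape does not match volume", call. = FALSE)
  invisible(TRUE)
}

#' Pairwise ROI metrics report for two or three image types
#'
#' Computes, for every lesion ROI and every ordered pair of image types
#' (e.g. STD = unfiltered, BF = bilateral-filtered, CNN = network output):
#' the SUVmax of each type, their absolute difference (g/mL) and symmetric
#' fractional difference (percent), plus per-pair liver-noise differences
#' (percentage points and percent) and the FLR of each type.
#'
#' @param vols named list of [pet_volume()] objects (2 or 3 image types).
#' @param rois a [roi_set()].
#' @return A data frame with one row per ROI (or liver) and comparison.
#' @export
metrics_report <- function(vols, rois) {
  stopifnot(is.list(vols), length(vols) >= 2L, !is.null(names(vols)),
            inherits(rois, "roi_set"))
  types <- names(vols)
  pairs <- utils::combn(types, 2L, simplify = FALSE)
  rows <- list()
  for (p in pairs) {
    a <- p[1]; b <- p[2]
    for (i in seq_along(rois$lesions)) {
      les <- rois$lesions[[i]]
      sa <- suv_max(vols[[a]], les); sb <- suv_max(vols[[b]], les)
      rows[[length(rows) + 1L]] <- data.frame(
        roi = les$label, metric = "SUVmax", type_a = a, type_b = b,
        value_a = sa, value_b = sb,
        delta = delta_abs(sa, sb), delta_pct = delta_frac(sa, sb),
        flr_a = flr(vols[[a]], les, rois$liver),
        flr_b = flr(vols[[b]], les, rois$liver),
        stringsAsFactors = FALSE)
    }
    na <- noise_level(vols[[a]], rois$liver)
    nb <- noise_level(vols[[b]], rois$liver)
    rows[[length(rows) + 1L]] <- data.frame(
      roi = rois$liver$label, metric = "Noise", type_a = a, type_b = b,
      value_a = na, value_b = nb,
      delta = delta_abs(na, nb), delta_pct = delta_frac(na, nb),
      flr_a = NA_real_, flr_b = NA_real_,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
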