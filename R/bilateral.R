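#' Derive anisotropic spatial sigmas from their reported mean
#'
#' The spatial kernel is anisotropic: its axial width is reduced by a
#' fixed scale factor (default 0.76) relative to the transaxial width to
#' account for the slightly higher axial resolution of reconstructed PET.
#' The single spatial parameter quoted to users, `sigma_s_mean`, is the
#' arithmetic mean `(2*sigma_xy + sigma_z)/3` of the per-axis widths, so
#' `sigma_xy = 3*sigma_s_mean/(2 + axial_scale)` and
#' `sigma_z = axial_scale * sigma_xy`.
#'
#' @param sigma_s_mean mean spatial sigma in mm (> 0).
#' @param axial_scale ratio `sigma_z / sigma_xy`, in (0, 1].
#' @return Named numeric: `sigma_xy`, `sigma_z` (mm).
#' @export
derive_sigmas <- function(sigma_s_mean, axial_scale = 0.76) {
  if (!is.finite(sigma_s_mean) || sigma_s_mean <= 0)
    stop("`sigma_s_mean` must be > 0", call. = FALSE)
  if (!is.finite(axial_scale) || axial_scale <= 0 || axial_scale > 1)
    stop("`axial_scale` must be in (0, 1]", call. = FALSE)
  sigma_xy <- 3 * sigma_s_mean / (2 + axial_scale)
  c(sigma_xy = sigma_xy, sigma_z = axial_scale * sigma_xy)
}

#' Bilateral filter parameters
#'
#' The two free parameters of the bilateral kernel: the (mean) spatial
#' standard deviation `sigma_s` in mm and the intensity standard deviation
#' `sigma_i` in SUV (g/mL). The anisotropic per-axis spatial sigmas are
#' derived via [derive_sigmas()] and stored alongside.
#'
#' @param sigma_s mean spatial sigma in mm.
#' @param sigma_i intensity sigma in SUV.
#' @param axial_scale axial width reduction factor (default 0.76).
#' @return An object of class `bf_params`.
#' @export
bf_params <- function(sigma_s, sigma_i, axial_scale = 0.76) {
  if (!is.finite(sigma_i) || sigma_i <= 0)
    stop("`sigma_i` must be > 0", call. = FALSE)
  s <- derive_sigmas(sigma_s, axial_scale)
  structure(list(sigma_s_mean = sigma_s, sigma_i = sigma_i,
                 sigma_xy = unname(s["sigma_xy"]), sigma_z = unname(s["sigma_z"]),
                 axial_scale = axial_scale),
            class = "bf_params")
}

#' @export
print.bf_params <- function(x, ...) {
  cat(sprintf(
    "<bf_params> sigma_s = %.4g mm (xy %.4g, z %.4g), sigma_i = %.4g SUV\n",
    x$sigma_s_mean, x$sigma_xy, x$sigma_z, x$sigma_i))
  invisible(x)
}

#' Kernel support specification
#'
#' The spatial kernel is truncated at `truncation_sigmas` spatial standard
#' deviations per axis; the per-axis voxel radius is
#' `ceil(truncation_sigmas * sigma_axis / spacing_axis)`. The intensity
#' term is never truncated. A radius of 0 on an axis means no neighbours
#' along that axis.
#'
#' @param params a [bf_params()].
#' @param spacing voxel spacing in mm (length 3).
#' @param truncation_sigmas dimensionless cutoff (default 3; Gaussian
#'   weights beyond 3 sigma are below 0.012).
#' @return An object of class `kernel_spec` with integer `radii`.
#' @export
kernel_spec <- function(params, spacing, truncation_sigmas = 3.0) {
  if (!is.finite(truncation_sigmas) || truncation_sigmas < 0)
    stop("`truncation_sigmas` must be >= 0", call. = FALSE)
  sig <- c(params$sigma_xy, params$sigma_xy, params$sigma_z)
  radii <- as.integer(ceiling(truncation_sigmas * sig / spacing))
  structure(list(truncation_sigmas = truncation_sigmas, radii = radii),
            class = "kernel_spec")
}

#' Bilateral kernel weight for a single voxel pair
#'
#' `W = exp(-(dx^2+dy^2)/(2 sigma_xy^2) - dz^2/(2 sigma_z^2)) *
#'      exp(-dI^2/(2 sigma_i^2))`, the product of the spatial and the
#' intensity Gaussian. Always in (0, 1]; equals 1 iff all deltas vanish.
#'
#' @param delta_pos mm offset, length 3 (x, y, z).
#' @param delta_intensity SUV difference.
#' @param params a [bf_params()].
#' @return Scalar weight.
#' @export
kernel_weight <- function(delta_pos, delta_intensity, params) {
  exp(-(delta_pos[1]^2 + delta_pos[2]^2) / (2 * params$sigma_xy^2) -
        delta_pos[3]^2 / (2 * params$sigma_z^2)) *
    exp(-delta_intensity^2 / (2 * params$sigma_i^2))
}

#' Reference bilateral filter (explicit loops)
#'
#' A deliberately naive per-voxel implementation of the same contract as
#' [bilateral_filter()], retained as the correctness oracle. Use only on
#' small volumes.
#'
#' @inheritParams bilateral_filter
#' @return A filtered [pet_volume()].
#' @export
bilateral_filter_reference <- function(vol, params, spec = NULL) {
  stopifnot(is_pet_volume(vol), inherits(params, "bf_params"))
  if (is.null(spec)) spec <- kernel_spec(params, vol$spacing)
  d <- dim(vol$data)
  r <- spec$radii
  out <- array(NA_real_, dim = d)
  x <- vol$data
  sp <- vol$spacing
  for (iz in seq_len(d[3])) for (iy in seq_len(d[2])) for (ix in seq_len(d[1])) {
    im <- x[ix, iy, iz]
    num <- 0; den <- 0
    for (dz in -r[3]:r[3]) {
      jz <- iz + dz
      if (jz < 1 || jz > d[3]) next
      for (dy in -r[2]:r[2]) {
        jy <- iy + dy
        if (jy < 1 || jy > d[2]) next
        for (dx in -r[1]:r[1]) {
          jx <- ix + dx
          if (jx < 1 || jx > d[1]) next
          w <- kernel_weight(c(dx, dy, dz) * sp, x[jx, jy, jz] - im, params)
          num <- num + w * x[jx, jy, jz]
          den <- den + w
        }
      }
    }
    out[ix, iy, iz] <- num / den
  }
  pet_volume(out, spacing = vol$spacing, origin = vol$origin)
}

#' Anisotropic 3D bilateral filter
#'
#' Edge-preserving weighted local average: the kernel is the product of an
#' anisotropic spatial Gaussian (widths `sigma_xy`, `sigma_z`) and an
#' intensity-difference Gaussian (width `sigma_i`), so only voxels close to
#' the target simultaneously in space and in intensity contribute. Borders
#' are handled by renormalising over the in-bounds neighbourhood; no
#' padding values are invented, so every output voxel is a convex
#' combination of observed input values. All accumulation is in double
#' precision and the result is deterministic.
#'
#' @param vol a [pet_volume()] in SUV units (filtering operates on SUV;
#'   no prior normalisation is applied).
#' @param params a [bf_params()].
#' @param spec a [kernel_spec()]; default truncation at 3 spatial sigmas.
#' @param mask optional logical array: compute output only at `TRUE`
#'   voxels (others are passed through). Exact at the masked voxels since
#'   each output depends only on input values.
#' @return A filtered [pet_volume()].
#' @export
bilateral_filter <- function(vol, params, spec = NULL, mask = NULL) {
  stopifnot(is_pet_volume(vol), inherits(params, "bf_params"))
  if (is.null(spec)) spec <- kernel_spec(params, vol$spacing)
  d <- dim(vol$data)
  if (!is.null(mask)) {
    stopifnot(identical(dim(mask), d))
    mask <- as.logical(mask)
  }
  out <- bf_filter_cpp(as.numeric(vol$data), as.integer(d),
                       as.numeric(vol$spacing),
                       params$sigma_xy, params$sigma_z, params$sigma_i,
                       as.integer(spec$radii), mask)
  pet_volume(array(out, dim = d), spacing = vol$spacing, origin = vol$origin)
}

#' Truncated, renormalised anisotropic Gaussian smoothing
#'
#' Separable Gaussian convolution with per-axis sigmas in mm, truncated at
#' `truncation_sigmas` and renormalised over the in-bounds support (same
#' border policy as the bilateral filter). This is the spatial-only limit
#' of the bilateral kernel (`sigma_i -> Inf`) and is used for the phantom
#' resolution blur.
#'
#' @param vol a [pet_volume()].
#' @param sigma_mm per-axis Gaussian sigma in mm (length 1 or 3).
#' @param truncation_sigmas support cutoff (default 3).
#' @return A smoothed [pet_volume()].
#' @export
gaussian_blur <- function(vol, sigma_mm, truncation_sigmas = 3.0) {
  stopifnot(is_pet_volume(vol))
  sigma_mm <- rep_len(as.numeric(sigma_mm), 3L)
  x <- vol$data
  d <- dim(x)
  for (ax in 1:3) {
    if (sigma_mm[ax] <= 0) next
    s_vox <- sigma_mm[ax] / vol$spacing[ax]
    r <- as.integer(ceiling(truncation_sigmas * s_vox))
    if (r < 1L) next
    k <- exp(-((-r:r)^2) / (2 * s_vox^2))
    x <- convolve_axis_renorm(x, k, ax)
  }
  pet_volume(x, spacing = vol$spacing, origin = vol$origin)
}

# 1D convolution along axis `ax` with kernel `k` (odd length), dividing by
# the sum of in-bounds kernel weights at each position.
convolve_axis_renorm <- function(x, k, ax) {
  d <- dim(x)
  n <- d[ax]
  r <- (length(k) - 1L) %/% 2L
  perm <- c(ax, setdiff(1:3, ax))
  xp <- aperm(x, perm)
  m <- matrix(xp, nrow = n)
  num <- matrix(0, nrow = n, ncol = ncol(m))
  den <- numeric(n)
  for (j in seq_along(k)) {
    off <- j - r - 1L
    src <- seq_len(n) + off
    ok <- src >= 1L & src <= n
    num[ok, ] <- num[ok, ] + k[j] * m[src[ok], , drop = FALSE]
    den[ok] <- den[ok] + k[j]
  }
  res <- num / den
  out <- array(res, dim = d[perm])
  aperm(out, order(perm))
}
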