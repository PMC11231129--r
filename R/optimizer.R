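#' Two-parameter grid for bilateral-filter optimization
#'
#' The default grid scans 11 spatial sigmas from 3.1 to 5.9 mm and 15
#' intensity sigmas from 0.1 to 10.0 SUV (165 combinations). Spatial
#' values are linearly spaced (a narrow range); intensity values are
#' geometrically spaced, since the range spans two orders of magnitude
#' while fitted values tend to cluster near 1 SUV, so a linear spacing
#' would concentrate most points where solutions are rare.
#'
#' @param s_range range of mean spatial sigma, mm.
#' @param i_range range of intensity sigma, SUV.
#' @param n_s,n_i number of grid values per axis.
#' @return An object of class `param_grid` with `sigma_s_values`
#'   and `sigma_i_values`.
#' @export
build_grid <- function(s_range = c(3.1, 5.9), i_range = c(0.1, 10.0),
                       n_s = 11L, n_i = 15L) {
  stopifnot(n_s >= 1L, n_i >= 1L)
  if (any(s_range <= 0) || any(i_range <= 0))
    stop("grid ranges must be strictly positive", call. = FALSE)
  if (n_s > 1L && s_range[1] >= s_range[2])
    stop("degenerate sigma_s range with n_s > 1", call. = FALSE)
  if (n_i > 1L && i_range[1] >= i_range[2])
    stop("degenerate sigma_i range with n_i > 1", call. = FALSE)
  sv <- if (n_s == 1L) s_range[1] else seq(s_range[1], s_range[2], length.out = n_s)
  iv <- if (n_i == 1L) i_range[1] else
    exp(seq(log(i_range[1]), log(i_range[2]), length.out = n_i))
  structure(list(sigma_s_values = sv, sigma_i_values = iv),
            class = "param_grid")
}

#' @export
print.param_grid <- function(x, ...) {
  cat(sprintf("<param_grid> %d x %d = %d combinations\n",
              length(x$sigma_s_values), length(x$sigma_i_values),
              length(x$sigma_s_values) * length(x$sigma_i_values)))
  invisible(x)
}

#' Number of filter jobs for a cohort scan
#'
#' Bookkeeping for the brute-force search: each single-gate volume is
#' filtered once per grid point, so a cohort of `n_volumes` volumes
#' scanned over `grid` requires `n_volumes * n_s * n_i` filter jobs.
#'
#' @param grid a [build_grid()] result.
#' @param n_volumes number of single-gate image volumes in the cohort.
#' @return Integer job count.
#' @export
scan_jobs <- function(grid, n_volumes) {
  stopifnot(inherits(grid, "param_grid"), n_volumes >= 0)
  as.integer(n_volumes) *
    length(grid$sigma_s_values) * length(grid$sigma_i_values)
}

#' Joint-gate objective for bilateral-filter parameter selection
#'
#' For a candidate parameter pair, every gate of the study is filtered and
#' the objective sums squared symmetric fractional differences:
#' over gates i and lesion ROIs j, the SUVmax change of the filtered gate
#' relative to the *unfiltered same gate*, plus over gates i the
#' liver-noise change of the filtered gate relative to the *unprocessed
#' ungated* image. Driving the noise terms to zero makes each filtered
#' gate match the ungated noise level; the SUVmax terms penalise signal
#' loss in focal uptake. Both delta families are in percent, so the
#' objective value is in squared percent.
#'
#' The optimization is performed jointly for all gates of a study (a
#' single parameter pair per study): gates of one gated acquisition share
#' noise, resolution and contrast properties, and the joint fit is more
#' stable than per-gate selection.
#'
#' @param study a [gated_study()].
#' @param rois a [roi_set()] (1 liver + >= 1 lesion masks).
#' @param params a [bf_params()].
#' @param spec optional [kernel_spec()].
#' @param masked if `TRUE` (default) filter only the ROI voxels — exact
#'   for this objective, since it reads filtered values only inside ROIs.
#' @return List: `S` (total), `suv_term`, `noise_term` (the two partial
#'   sums; `S = suv_term + noise_term` exactly), and per-gate details.
#' @export
bf_objective <- function(study, rois, params, spec = NULL, masked = TRUE) {
  stopifnot(inherits(study, "gated_study"), inherits(rois, "roi_set"))
  if (is.null(spec)) spec <- kernel_spec(params, study$ungated$spacing)
  roi_union <- if (masked) roi_union_mask(rois) else NULL
  noise_ref <- noise_level(study$ungated, rois$liver)
  suv_term <- 0; noise_term <- 0
  per_gate <- vector("list", study$gate_count)
  for (i in seq_len(study$gate_count)) {
    gate <- study$gates[[i]]
    filt <- bilateral_filter(gate, params, spec, mask = roi_union)
    d_suv <- vapply(rois$lesions, function(les)
      delta_frac(suv_max(filt, les), suv_max(gate, les)), numeric(1))
    d_noise <- delta_frac(noise_level(filt, rois$liver), noise_ref)
    suv_term <- suv_term + sum(d_suv^2)
    noise_term <- noise_term + d_noise^2
    per_gate[[i]] <- list(delta_suvmax = d_suv, delta_noise = d_noise)
  }
  list(S = suv_term + noise_term, suv_term = suv_term,
       noise_term = noise_term, per_gate = per_gate)
}

roi_union_mask <- function(rois) {
  u <- rois$liver$mask
  for (m in rois$lesions) u <- u | m$mask
  u
}

#' Tie-breaking rule for equal objective values
#'
#' Among grid points whose objective values agree within relative
#' tolerance, the candidate with the smallest intensity sigma wins, then
#' the smallest spatial sigma: the least intensity-smoothing solution is
#' preferred, guarding against over-smoothing.
#'
#' @param candidates matrix or list of index pairs `(i_s, i_i)` (1-based).
#' @param grid the [build_grid()] the indices refer to.
#' @return A single index pair `c(i_s, i_i)`.
#' @export
tie_break <- function(candidates, grid) {
  if (is.list(candidates)) candidates <- do.call(rbind, candidates)
  candidates <- matrix(as.integer(candidates), ncol = 2L)
  stopifnot(nrow(candidates) >= 1L)
  si <- grid$sigma_i_values[candidates[, 2]]
  ss <- grid$sigma_s_values[candidates[, 1]]
  candidates[order(si, ss)[1L], ]
}

#' Brute-force grid search for case-optimal filter parameters
#'
#' Evaluates [bf_objective()] at every grid point and returns the global
#' argmin together with the full objective surface for audit. Evaluation
#' is deterministic and independent of traversal order. Grid points where
#' a metric is undefined (e.g. non-positive liver mean) are recorded as
#' invalid (`NA` in the surface) and excluded from the argmin.
#'
#' @inheritParams bf_objective
#' @param grid a [build_grid()].
#' @param axial_scale passed to [bf_params()].
#' @param truncation_sigmas passed to [kernel_spec()].
#' @param verbose print per-point progress (165-point scans are long).
#' @return List of class `bf_search`: `best` ([bf_params()]), `surface`
#'   (matrix of S values, sigma_s in rows), `suv_terms`, `noise_terms`,
#'   `argmin` (index pair), `grid`, `provenance` (`"grid_search"`).
#' @export
bf_grid_search <- function(study, rois, grid = build_grid(),
                           axial_scale = 0.76, truncation_sigmas = 3.0,
                           masked = TRUE, verbose = FALSE) {
  stopifnot(inherits(grid, "param_grid"))
  ns <- length(grid$sigma_s_values); ni <- length(grid$sigma_i_values)
  surface <- matrix(NA_real_, ns, ni,
                    dimnames = list(
                      sprintf("sS=%.3g", grid$sigma_s_values),
                      sprintf("sI=%.3g", grid$sigma_i_values)))
  suv_terms <- noise_terms <- surface
  for (is in seq_len(ns)) {
    for (ii in seq_len(ni)) {
      p <- bf_params(grid$sigma_s_values[is], grid$sigma_i_values[ii],
                     axial_scale = axial_scale)
      sp <- kernel_spec(p, study$ungated$spacing, truncation_sigmas)
      res <- tryCatch(bf_objective(study, rois, p, sp, masked = masked),
                      error = function(e) NULL)
      if (is.null(res)) next
      surface[is, ii] <- res$S
      suv_terms[is, ii] <- res$suv_term
      noise_terms[is, ii] <- res$noise_term
      if (verbose)
        message(sprintf("grid point (%d,%d): sS=%.3g sI=%.3g S=%.4g",
                        is, ii, p$sigma_s_mean, p$sigma_i, res$S))
    }
  }
  if (all(is.na(surface)))
    stop("optimization failed: objective undefined at every grid point",
         call. = FALSE)
  smin <- min(surface, na.rm = TRUE)
  tol <- 1e-12 * max(1, abs(smin))
  cand <- which(!is.na(surface) & surface <= smin + tol, arr.ind = TRUE)
  argmin <- tie_break(cand, grid)
  best <- bf_params(grid$sigma_s_values[argmin[1]],
                    grid$sigma_i_values[argmin[2]],
                    axial_scale = axial_scale)
  structure(list(best = best, surface = surface, suv_terms = suv_terms,
                 noise_terms = noise_terms, argmin = argmin, grid = grid,
                 provenance = "grid_search"),
            class = "bf_search")
}

#' @export
print.bf_search <- function(x, ...) {
  cat(sprintf(
    "<bf_search> best sigma_s = %.4g mm, sigma_i = %.4g SUV (S = %.5g)\n",
    x$best$sigma_s_mean, x$best$sigma_i,
    x$surface[x$argmin[1], x$argmin[2]]))
  invisible(x)
}

#' Record manually chosen filter parameters
#'
#' Visual inspection can overrule the automated selection (over-smoothing
#' or edge artifacts are the usual reasons). This wraps a user-supplied
#' parameter pair in the same result structure as [bf_grid_search()],
#' marked `"manual"` in provenance.
#'
#' @param params a [bf_params()].
#' @return A `bf_search`-classed list with provenance `"manual"`.
#' @export
manual_params <- function(params) {
  stopifnot(inherits(params, "bf_params"))
  structure(list(best = params, surface = NULL, suv_terms = NULL,
                 noise_terms = NULL, argmin = NULL, grid = NULL,
                 provenance = "manual"),
            class = "bf_search")
}
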