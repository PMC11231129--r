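test_that("default grid has the canonical shape and spacing", {
  g <- build_grid()
  expect_length(g$sigma_s_values, 11)
  expect_length(g$sigma_i_values, 15)
  expect_equal(length(g$sigma_s_values) * length(g$sigma_i_values), 165)
  expect_equal(g$sigma_s_values, seq(3.1, 5.9, by = 0.28), tolerance = 1e-12)
  expect_equal(range(g$sigma_i_values), c(0.1, 10.0), tolerance = 1e-12)
  # geometric spacing: constant ratio
  ratios <- g$sigma_i_values[-1] / g$sigma_i_values[-15]
  expect_equal(max(ratios) - min(ratios), 0, tolerance = 1e-10)

  g1 <- build_grid(n_s = 1, n_i = 1)
  expect_equal(g1$sigma_s_values, 3.1)
  expect_equal(g1$sigma_i_values, 0.1)
  expect_error(build_grid(s_range = c(3, 3), n_s = 2), "degenerate")
})

test_that("scan bookkeeping multiplies volumes by grid points", {
  expect_identical(scan_jobs(build_grid(), 552), 91080L)
  expect_identical(scan_jobs(build_grid(n_s = 5, n_i = 7), 3), 105L)
  expect_identical(scan_jobs(build_grid(), 0), 0L)
})

test_that("objective vanishes for an identity filter on noise-matched gates", {
  # gates identical to the ungated volume: no SUVmax change under the
  # identity (radius-0) filter and no noise mismatch
  v <- random_volume(c(8, 8, 6), seed = 1, lo = 1, hi = 3)
  study <- gated_study(list(v, v, v), ungated = v)
  m <- array(FALSE, dim = dim(v$data)); m[1:40] <- TRUE
  liver <- roi_mask(m, role = "liver")
  m2 <- array(FALSE, dim = dim(v$data)); m2[200:210] <- TRUE
  rois <- roi_set(liver, list(roi_mask(m2, role = "lesion")))
  p <- bf_params(4.0, 1.0)
  spec0 <- kernel_spec(p, v$spacing, truncation_sigmas = 0)
  res <- bf_objective(study, rois, p, spec0)
  expect_equal(res$S, 0, tolerance = 1e-20)
  expect_equal(res$suv_term, 0)
  expect_equal(res$noise_term, 0)
})

test_that("identity-filter objective equals the closed-form noise mismatch", {
  # gates with higher noise than the ungated reference: SUVmax terms are 0
  # under the identity filter and each noise term is the same closed form
  ph <- generate_phantom(small_phantom_config(seed = 2))
  p <- bf_params(4.0, 1.0)
  spec0 <- kernel_spec(p, ph$study$ungated$spacing, truncation_sigmas = 0)
  res <- bf_objective(ph$study, ph$rois, p, spec0)
  expect_equal(res$suv_term, 0, tolerance = 1e-18)
  n_ref <- noise_level(ph$study$ungated, ph$rois$liver)
  expected <- sum(vapply(ph$study$gates, function(g)
    delta_frac(noise_level(g, ph$rois$liver), n_ref)^2, numeric(1)))
  expect_equal(res$noise_term, expected, tolerance = 1e-10)
  expect_equal(res$S, res$suv_term + res$noise_term, tolerance = 1e-12)
})

test_that("objective equals independent recomputation at several grid points", {
  ph <- generate_phantom(small_phantom_config(seed = 5, gate_count = 3L))
  grid <- build_grid(c(3.5, 5.0), c(0.5, 5.0), n_s = 2, n_i = 2)
  n_ref <- noise_level(ph$study$ungated, ph$rois$liver)
  for (is in 1:2) for (ii in 1:2) {
    p <- bf_params(grid$sigma_s_values[is], grid$sigma_i_values[ii])
    res <- bf_objective(ph$study, ph$rois, p)
    # independent route: full-volume filtering, metrics assembled by hand
    S_manual <- 0
    for (g in ph$study$gates) {
      filt <- bilateral_filter(g, p)
      for (les in ph$rois$lesions) {
        d <- delta_frac(suv_max(filt, les), suv_max(g, les))
        S_manual <- S_manual + d^2
      }
      dn <- delta_frac(noise_level(filt, ph$rois$liver), n_ref)
      S_manual <- S_manual + dn^2
    }
    expect_equal(res$S, S_manual, tolerance = 1e-10)
    expect_equal(res$S, res$suv_term + res$noise_term, tolerance = 1e-12)
    expect_gte(res$S, 0)
  }
})

test_that("grid search returns the exhaustive argmin with surface audit", {
  ph <- generate_phantom(small_phantom_config(seed = 6, gate_count = 2L))
  grid <- build_grid(c(3.5, 5.5), c(0.3, 3.0), n_s = 2, n_i = 2)
  sr <- bf_grid_search(ph$study, ph$rois, grid)
  # exhaustive oracle: recompute all four S values independently
  vals <- matrix(NA_real_, 2, 2)
  for (is in 1:2) for (ii in 1:2)
    vals[is, ii] <- bf_objective(
      ph$study, ph$rois,
      bf_params(grid$sigma_s_values[is], grid$sigma_i_values[ii]))$S
  expect_equal(unname(sr$surface), vals, tolerance = 1e-10)
  best_idx <- which(vals == min(vals), arr.ind = TRUE)[1, ]
  expect_equal(unname(sr$argmin), unname(best_idx))
  expect_equal(sr$best$sigma_s_mean, grid$sigma_s_values[best_idx[1]])
  expect_equal(sr$best$sigma_i, grid$sigma_i_values[best_idx[2]])
  # conservation at every point
  expect_equal(sr$surface, sr$suv_terms + sr$noise_terms, tolerance = 1e-12)
})

test_that("1x1 grid returns its only point", {
  ph <- generate_phantom(small_phantom_config(seed = 7, gate_count = 1L))
  grid <- build_grid(c(4.0, 5.0), c(1.0, 2.0), n_s = 1, n_i = 1)
  sr <- bf_grid_search(ph$study, ph$rois, grid)
  expect_equal(sr$best$sigma_s_mean, 4.0)
  expect_equal(sr$best$sigma_i, 1.0)
  expect_equal(dim(sr$surface), c(1L, 1L))
})

test_that("tie-breaking prefers smaller sigma_i, then smaller sigma_s", {
  grid <- build_grid(c(3, 5), c(0.5, 2), n_s = 3, n_i = 3)
  expect_equal(tie_break(matrix(c(2, 2), 1), grid), c(2, 2))
  expect_equal(tie_break(rbind(c(1, 3), c(3, 1)), grid), c(3, 1))
  expect_equal(tie_break(rbind(c(2, 1), c(1, 1), c(3, 2)), grid), c(1, 1))
  # constant image: all S equal, argmin must land on the min-sigma corner
  v <- pet_volume(array(2, dim = c(8, 8, 6)))
  study <- gated_study(list(v, v), ungated = v)
  m <- array(FALSE, dim = dim(v$data)); m[1:30] <- TRUE
  m2 <- array(FALSE, dim = dim(v$data)); m2[100:110] <- TRUE
  rois <- roi_set(roi_mask(m, role = "liver"),
                  list(roi_mask(m2, role = "lesion")))
  sr <- bf_grid_search(study, rois, grid)
  expect_equal(unname(sr$argmin), c(1, 1))
})

test_that("manual parameter override carries manual provenance", {
  mp <- manual_params(bf_params(4.2, 1.3))
  expect_s3_class(mp, "bf_search")
  expect_equal(mp$provenance, "manual")
  expect_equal(mp$best$sigma_s_mean, 4.2)
})
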