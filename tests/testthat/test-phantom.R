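test_that("noiseless motionless phantom gates equal the truth volume", {
  ph <- generate_phantom(small_phantom_config(seed = 1, noise_cv = 0,
                                              motion_amplitude = 0))
  for (g in ph$study$gates)
    expect_equal(g$data, ph$truth$data, tolerance = 1e-14)
  expect_equal(ph$study$ungated$data, ph$truth$data, tolerance = 1e-14)
})

test_that("per-gate liver CV matches the configured noise level", {
  for (seed in c(2, 3)) {
    ph <- generate_phantom(small_phantom_config(seed = seed, noise_cv = 15))
    expect_gt(sum(ph$rois$liver$mask), 100)
    for (i in c(1, 4, 8)) {
      cv <- noise_level(ph$study$gates[[i]], ph$rois$liver)
      expect_equal(cv, 15, tolerance = 1.5)   # within 10% relative
    }
  }
})

test_that("independent gate noise averages down by sqrt(g) in the ungated sum", {
  # uncorrelated-noise mode: noise_corr_vox = 0
  ratios <- vapply(1:20, function(seed) {
    cfg <- small_phantom_config(seed = seed)
    cfg$noise_corr_vox <- 0
    ph <- generate_phantom(cfg)
    noise_level(ph$study$ungated, ph$rois$liver) /
      noise_level(ph$study$gates[[1]], ph$rois$liver)
  }, numeric(1))
  expect_equal(mean(ratios), 1 / sqrt(8), tolerance = 0.12)
})

test_that("lesion SUVmax in the noiseless truth follows the blurred peaks", {
  cfg <- small_phantom_config(seed = 4, noise_cv = 0, motion_amplitude = 0)
  ph <- generate_phantom(cfg)
  peaks <- vapply(cfg$lesions, function(l) l$peak, numeric(1))
  got <- vapply(ph$rois$lesions, function(r) suv_max(ph$truth, r), numeric(1))
  # ordering preserved
  expect_identical(order(got), order(peaks))
  # analytic sphere-blur oracle: peak of a uniform sphere (contrast above
  # its surround) blurred by an isotropic Gaussian, evaluated at centre:
  # c(r) = erf(r/(s*sqrt(2))) - sqrt(2/pi)*(r/s)*exp(-r^2/(2 s^2))
  s <- cfg$psf_fwhm / 2.3548
  r <- cfg$lesions[[1]]$radius
  recov <- function(r, s) {
    z <- r / s
    pracma::erf(z / sqrt(2)) - sqrt(2 / pi) * z * exp(-z^2 / 2)
  }
  for (i in seq_along(cfg$lesions)) {
    bg <- cfg$liver$uptake  # lesions sit inside the liver
    expected <- bg + (peaks[i] - bg) * recov(cfg$lesions[[i]]$radius, s)
    expect_equal(got[i], expected, tolerance = 0.05 * expected)
  }
})

test_that("gate displacement along z matches the motion amplitude", {
  cfg <- small_phantom_config(seed = 5, noise_cv = 0, motion_amplitude = 6)
  ph <- generate_phantom(cfg)
  centroid_z <- function(vol, roi) {
    w <- vol$data[roi$mask]
    zs <- arrayInd(which(roi$mask), dim(vol$data))[, 3]
    # half-max segmentation isolates the lesion from the liver background
    keep <- w >= (max(w) + min(w)) / 2
    sum(w[keep] * zs[keep]) / sum(w[keep])
  }
  # phase i and i + g/2 are displaced in opposite directions; the pair at
  # the extremes of cos differs by the full amplitude
  les <- ph$rois$lesions[[3]]
  z4 <- centroid_z(ph$study$gates[[4]], les)   # cos(pi) = -1
  z8 <- centroid_z(ph$study$gates[[8]], les)   # cos(2 pi) = +1
  diff_mm <- (z8 - z4) * cfg$spacing[3]
  expect_equal(diff_mm, cfg$motion_amplitude, tolerance = cfg$spacing[3])
})

test_that("phantom regeneration from provenance is bit-identical", {
  dir <- withr::local_tempdir()
  ph <- generate_phantom(small_phantom_config(seed = 9))
  man <- save_phantom_study(ph, dir)
  ph2 <- regenerate_from_provenance(man)
  for (i in seq_len(ph$config$gate_count))
    expect_identical(ph2$study$gates[[i]]$data, ph$study$gates[[i]]$data)
  expect_identical(ph2$study$ungated$data, ph$study$ungated$data)
  expect_identical(ph2$rois$liver$mask, ph$rois$liver$mask)
})

test_that("seed and noise level isolate the phantom components", {
  base <- generate_phantom(small_phantom_config(seed = 10))
  other_seed <- generate_phantom(small_phantom_config(seed = 11))
  expect_false(identical(base$study$gates[[1]]$data,
                         other_seed$study$gates[[1]]$data))
  cfg <- small_phantom_config(seed = 10, noise_cv = 10)
  other_cv <- generate_phantom(cfg)
  expect_identical(other_cv$truth$data, base$truth$data)
  for (i in seq_along(base$truth_gates))
    expect_identical(other_cv$truth_gates[[i]]$data,
                     base$truth_gates[[i]]$data)
  expect_false(identical(other_cv$study$gates[[1]]$data,
                         base$study$gates[[1]]$data))
})

test_that("phantom config validation catches bad geometry and contrast", {
  expect_error(phantom_config(lesions = list(
    list(center = c(0, 0, 0), radius = 8, peak = 4),
    list(center = c(5, 0, 0), radius = 8, peak = 5))),
    "ratio")
  expect_error(phantom_config(lesions = list(
    list(center = c(500, 0, 0), radius = 8, peak = 4))),
    "outside")
  expect_error(phantom_config(lesions = list(
    list(center = c(0, 0, 0), radius = 8, peak = 8),
    list(center = c(30, 0, 0), radius = 8, peak = 4))),
    "ascending")
})

test_that("ungated volume is the voxel-wise mean of the gates", {
  ph <- generate_phantom(small_phantom_config(seed = 12, gate_count = 4L))
  acc <- Reduce(`+`, lapply(ph$study$gates, function(g) g$data)) / 4
  expect_equal(ph$study$ungated$data, acc, tolerance = 1e-14)
})
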