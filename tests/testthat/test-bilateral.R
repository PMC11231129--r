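test_that("derive_sigmas inverts the anisotropic mean convention", {
  expect_equal(derive_sigmas(2.76, 0.76),
               c(sigma_xy = 3.0, sigma_z = 2.28), tolerance = 1e-12)
  expect_equal(derive_sigmas(5.0, 1.0),
               c(sigma_xy = 5.0, sigma_z = 5.0), tolerance = 1e-12)
  # independent solve of the 2x2 linear system
  #   2*sxy + sz = 3*mean ; sz - scale*sxy = 0
  for (mean_s in c(3.1, 4.9, 5.9)) {
    for (sc in c(0.5, 0.76, 1.0)) {
      sol <- unname(solve(matrix(c(2, -sc, 1, 1), 2, 2), c(3 * mean_s, 0)))
      got <- derive_sigmas(mean_s, sc)
      expect_equal(unname(got["sigma_xy"]), sol[1], tolerance = 1e-12)
      expect_equal(unname(got["sigma_z"]), sol[2], tolerance = 1e-12)
      expect_equal((2 * got[["sigma_xy"]] + got[["sigma_z"]]) / 3, mean_s,
                   tolerance = 1e-12)
    }
  }
  expect_equal(unname(derive_sigmas(4.9, 0.76)),
               c(5.32608695652174, 4.04782608695652), tolerance = 1e-10)
  expect_error(derive_sigmas(-1), "> 0")
  expect_error(derive_sigmas(3, 1.5), "0, 1")
})

test_that("kernel_weight matches the product-Gaussian form", {
  p <- bf_params(4.5, 0.8)
  expect_equal(kernel_weight(c(0, 0, 0), 0, p), 1.0)
  expect_equal(kernel_weight(c(p$sigma_xy, 0, 0), 0, p), exp(-0.5))
  expect_equal(kernel_weight(c(0, 0, p$sigma_z), 0, p), exp(-0.5))
  expect_equal(kernel_weight(c(0, 0, 0), 2 * p$sigma_i, p), exp(-2))
  # separability: spatial and intensity parts multiply
  w <- kernel_weight(c(2, 3, 1), 0.4, p)
  expect_equal(w, kernel_weight(c(2, 3, 1), 0, p) *
                 kernel_weight(c(0, 0, 0), 0.4, p), tolerance = 1e-14)
  expect_true(w > 0 && w <= 1)
})

test_that("reference filter is identity on constant input and radius 0", {
  p <- bf_params(4.0, 1.0)
  const <- pet_volume(array(1.7, dim = c(5, 5, 5)))
  out <- bilateral_filter_reference(const, p)
  expect_equal(out$data, const$data, tolerance = 1e-14)

  v <- random_volume(c(5, 5, 5), seed = 2)
  spec0 <- kernel_spec(p, v$spacing, truncation_sigmas = 0)
  expect_identical(spec0$radii, c(0L, 0L, 0L))
  expect_equal(bilateral_filter_reference(v, p, spec0)$data, v$data,
               tolerance = 1e-14)
})

test_that("production filter equals the loop reference on random volumes", {
  p <- bf_params(4.9, 1.0)
  for (seed in 1:6) {
    v <- random_volume(c(8, 8, 8), seed = seed)
    ref <- bilateral_filter_reference(v, p)
    got <- bilateral_filter(v, p)
    expect_lt(max(abs(got$data - ref$data) / pmax(abs(ref$data), 1e-12)),
              1e-6)
  }
})

test_that("masked filtering is exact at the masked voxels", {
  v <- random_volume(c(10, 9, 8), seed = 5)
  p <- bf_params(4.0, 0.8)
  full <- bilateral_filter(v, p)
  set.seed(6)
  mask <- array(runif(prod(dim(v$data))) < 0.3, dim = dim(v$data))
  part <- bilateral_filter(v, p, mask = mask)
  expect_equal(part$data[mask], full$data[mask], tolerance = 1e-14)
  expect_equal(part$data[!mask], v$data[!mask], tolerance = 1e-14)
})

test_that("sigma_i -> Inf degenerates to renormalised Gaussian smoothing", {
  v <- random_volume(c(9, 9, 7), seed = 7)
  p <- bf_params(4.9, 1e9)
  got <- bilateral_filter(v, p)
  s <- derive_sigmas(4.9)
  ref <- gaussian_blur(v, c(s[["sigma_xy"]], s[["sigma_xy"]], s[["sigma_z"]]))
  expect_lt(max(abs(got$data - ref$data) / pmax(abs(ref$data), 1e-12)), 1e-4)
})

test_that("output is a convex combination of the kernel neighbourhood", {
  p <- bf_params(3.5, 0.5)
  for (seed in c(3, 9)) {
    v <- random_volume(c(8, 8, 8), seed = seed, lo = 0, hi = 10)
    out <- bilateral_filter(v, p)
    expect_true(all(out$data >= min(v$data) - 1e-12))
    expect_true(all(out$data <= max(v$data) + 1e-12))
    # per-voxel neighbourhood bound with the actual kernel radii
    spec <- kernel_spec(p, v$spacing)
    d <- dim(v$data)
    for (idx in list(c(1, 1, 1), c(4, 5, 3), c(8, 8, 8))) {
      rng <- lapply(1:3, function(a)
        max(1, idx[a] - spec$radii[a]):min(d[a], idx[a] + spec$radii[a]))
      nb <- v$data[rng[[1]], rng[[2]], rng[[3]]]
      val <- out$data[idx[1], idx[2], idx[3]]
      expect_gte(val, min(nb) - 1e-12)
      expect_lte(val, max(nb) + 1e-12)
    }
  }
})

test_that("bilateral filtering preserves step edges where Gaussian blurs them", {
  # narrow hot slab (lesion-like): its edges step between levels that
  # differ by 18 sigma_i; spatial smoothing erodes the plateau and moves
  # the 50%-crossing of the profile, the bilateral filter does not
  n <- c(28, 9, 9)
  arr <- array(1, dim = n)
  arr[17:19, , ] <- 10
  v <- pet_volume(arr, spacing = c(3.3, 3.3, 2.0))
  p <- bf_params(4.9, 0.5)            # levels differ by 18 sigma_i
  bf <- bilateral_filter(v, p)
  s <- derive_sigmas(4.9)
  gs <- gaussian_blur(v, c(s[["sigma_xy"]], s[["sigma_xy"]], s[["sigma_z"]]))

  crossing <- function(vol) {
    prof <- vol$data[, 5, 5]
    mid <- (min(prof) + max(prof)) / 2
    i <- which(prof >= mid)[1]
    # linear interpolation of the 50% crossing position (voxel units)
    (i - 1) + (mid - prof[i - 1]) / (prof[i] - prof[i - 1])
  }
  true_cross <- crossing(v)
  expect_lt(abs(crossing(bf) - true_cross), 0.1)
  expect_gt(abs(crossing(gs) - true_cross), 0.5)
})

test_that("kernel_spec radii follow the truncation rule", {
  p <- bf_params(4.9, 1)
  sp <- kernel_spec(p, c(3.3, 3.3, 2.0), truncation_sigmas = 3)
  s <- derive_sigmas(4.9)
  expect_identical(sp$radii,
                   as.integer(ceiling(3 * c(s[1], s[1], s[2]) / c(3.3, 3.3, 2.0))))
})
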