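test_that("joint normalization maps the pair range onto [0, 1] and inverts", {
  a <- pet_volume(array(seq(0, 10, length.out = 64), dim = c(4, 4, 4)))
  b <- pet_volume(array(seq(2, 8, length.out = 64), dim = c(4, 4, 4)))
  nz <- normalize_pair(a, b)
  expect_equal(nz$record$offset, 0)
  expect_equal(nz$record$scale, 10)
  # the joint [0, 10] range maps SUV v to v/10: SUV 5 -> 0.5
  expect_equal(nz$unfiltered$data, a$data / 10, tolerance = 1e-12)
  expect_equal(nz$filtered$data, b$data / 10, tolerance = 1e-12)
  back <- invert_norm(nz$unfiltered, nz$record)
  expect_equal(back$data, a$data, tolerance = 1e-12)

  # property: both normalized volumes always land in [0, 1]
  for (seed in 1:10) {
    set.seed(seed)
    u <- suppressWarnings(pet_volume(array(runif(27, -2, 12), dim = c(3, 3, 3))))
    f <- suppressWarnings(pet_volume(array(runif(27, -1, 9), dim = c(3, 3, 3))))
    nz <- normalize_pair(u, f)
    expect_true(all(nz$unfiltered$data >= 0 & nz$unfiltered$data <= 1))
    expect_true(all(nz$filtered$data >= 0 & nz$filtered$data <= 1))
    expect_equal(suppressWarnings(invert_norm(nz$filtered, nz$record))$data,
                 f$data, tolerance = 1e-9)
  }
  const <- pet_volume(array(3, dim = c(3, 3, 3)))
  expect_error(normalize_pair(const, const), "degenerate")
})

test_that("patch corner lattice covers every voxel at stride <= 24", {
  expect_identical(patch_corners(32), 0L)
  expect_identical(patch_corners(56), c(0L, 24L))
  # overlap at 56: patches [0,32) and [24,56) share 8 voxels = 25%
  expect_equal(32 - 24, 8)
  expect_error(patch_corners(20), "smaller than")

  for (n in c(32, 33, 56, 60, 132, 140, 153, 220)) {
    cs <- patch_corners(n)
    expect_lte(max(diff(c(cs, n - 32))), 24)
    covered <- logical(n)
    for (c0 in cs) covered[(c0 + 1):(c0 + 32)] <- TRUE
    expect_true(all(covered))
    # minimum 25% overlap between adjacent patches
    if (length(cs) > 1)
      expect_true(all(32 - diff(cs) >= 8))
  }
})

test_that("extract_patch_pairs tiles a volume into co-located 32-cubes", {
  u <- random_volume(c(56, 32, 40), seed = 1, lo = 0, hi = 1)
  f <- random_volume(c(56, 32, 40), seed = 2, lo = 0, hi = 1)
  pairs <- extract_patch_pairs(u, f)
  expect_length(pairs, 2 * 1 * 2)
  for (p in pairs) {
    expect_identical(dim(p$input), c(32L, 32L, 32L))
    ix <- (p$corner[1] + 1):(p$corner[1] + 32)
    iy <- (p$corner[2] + 1):(p$corner[2] + 32)
    iz <- (p$corner[3] + 1):(p$corner[3] + 32)
    expect_identical(p$input, u$data[ix, iy, iz])
    expect_identical(p$target, f$data[ix, iy, iz])
  }
})

test_that("gamma exponent follows the (1+|G|)^sign(G) construction", {
  expect_equal(gamma_value(0), 1)
  expect_equal(gamma_value(1), 2)
  expect_equal(gamma_value(-1), 0.5)
  expect_equal(gamma_value(0.5), 1.5)
  expect_equal(gamma_value(-0.5), 1 / 1.5, tolerance = 1e-12)
  expect_true(all(gamma_value(rnorm(100)) > 0))
})

test_that("log gamma is symmetric about zero over many draws", {
  set.seed(20)
  g <- gamma_value(rnorm(1e5, 0, 0.5))
  lg <- log(g)
  skew <- mean((lg - mean(lg))^3) / stats::sd(lg)^3
  expect_lt(abs(skew), 0.05)
  expect_lt(abs(mean(lg)), 0.01)
})

test_that("augmentation applies flips and gamma identically to both patches", {
  set.seed(21)
  x <- array(runif(8^3), dim = c(8, 8, 8))
  pair <- structure(list(input = x, target = x, corner = c(0L, 0L, 0L)),
                    class = "patch_pair")
  # metamorphic: an identical pair stays identical under any augmentation
  for (seed in 1:20) {
    aug <- augment_pair(pair, seed = seed)
    expect_identical(aug$input, aug$target)
    expect_true(all(aug$input >= 0 & aug$input <= 1))
  }
  # deterministic given seed
  p2 <- structure(list(input = x, target = x^2, corner = c(0L, 0L, 0L)),
                  class = "patch_pair")
  a1 <- augment_pair(p2, seed = 7)
  a2 <- augment_pair(p2, seed = 7)
  expect_identical(a1$input, a2$input)
  expect_identical(a1$target, a2$target)
  # gamma map fixes 0 and 1
  px <- array(0, dim = c(4, 4, 4)); px[1:32] <- 1
  pf <- structure(list(input = px, target = px, corner = c(0L, 0L, 0L)),
                  class = "patch_pair")
  aug <- augment_pair(pf, seed = 3)
  expect_setequal(unique(as.vector(aug$input)), c(0, 1))
  # the value transform is a single monotone power map: the sorted
  # augmented values equal the sorted originals raised to one gamma
  a3 <- augment_pair(p2, seed = 9)
  sx <- sort(as.vector(p2$input))
  sa <- sort(as.vector(a3$input))
  gam <- log(sa[100]) / log(sx[100])
  expect_gt(gam, 0)
  expect_equal(sa, sx^gam, tolerance = 1e-10)
})

test_that("normalize_volume round-trips a single volume", {
  v <- random_volume(c(6, 6, 6), seed = 30, lo = 0.2, hi = 7)
  nz <- normalize_volume(v)
  expect_equal(range(nz$vol$data), c(0, 1), tolerance = 1e-12)
  expect_equal(invert_norm(nz$vol, nz$record)$data, v$data, tolerance = 1e-9)
})
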