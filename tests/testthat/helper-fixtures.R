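# Fixtures are generated in code at test time; no binary data ships with
# the package.

random_volume <- function(n = c(8, 8, 8), seed = 1, lo = 0.5, hi = 3,
                          spacing = c(3.3, 3.3, 2.0)) {
  set.seed(seed)
  pet_volume(array(runif(prod(n), lo, hi), dim = n), spacing = spacing)
}

# a reduced-geometry phantom for fast unit tests (the default
# phantom_config() is the full study-conditions phantom)
small_phantom_config <- function(seed = 1, noise_cv = 15,
                                 motion_amplitude = 6, gate_count = 8L) {
  phantom_config(
    shape = c(32L, 32L, 24L), spacing = c(3.3, 3.3, 2.0),
    gate_count = gate_count,
    liver = list(center = NULL, semiaxes = c(40, 30, 18), uptake = 2.0),
    lesions = list(
      list(center = c(-22, -8, 0), radius = 6, peak = 4),
      list(center = c(0, 14, 2),   radius = 6, peak = 6),
      list(center = c(22, -8, -2), radius = 6, peak = 12)),
    motion_amplitude = motion_amplitude, noise_cv = noise_cv,
    psf_fwhm = 4, roi_margin = 6, seed = seed)
}

# random 32^3 normalized patch pair with smooth target, for training tests
random_patch_pair <- function(n = 8L, seed = 1) {
  set.seed(seed)
  x <- array(runif(n^3, 0.1, 0.9), dim = c(n, n, n))
  structure(list(input = x, target = x, corner = c(0L, 0L, 0L)),
            class = "patch_pair")
}
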