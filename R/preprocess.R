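#' Joint [0, 1] normalization of an unfiltered/filtered volume pair
#'
#' A single affine map, computed from the joint min/max of the two
#' volumes, sends both into [0, 1]. Using one shared map keeps the
#' residual-learning target consistent (the same SUV maps to the same
#' normalized value in input and target) and one record inverts both.
#'
#' @param unfiltered,filtered congruent [pet_volume()] objects.
#' @return List: `unfiltered`, `filtered` (normalized volumes), `record`
#'   (class `norm_record` with `offset` = SUV mapped to 0 and `scale` =
#'   SUV range mapped to 1).
#' @export
normalize_pair <- function(unfiltered, filtered) {
  stopifnot(is_pet_volume(unfiltered), is_pet_volume(filtered),
            same_geometry(unfiltered, filtered))
  lo <- min(min(unfiltered$data), min(filtered$data))
  hi <- max(max(unfiltered$data), max(filtered$data))
  if (hi <= lo)
    stop("degenerate normalization: joint intensity range is empty",
         call. = FALSE)
  rec <- structure(list(offset = lo, scale = hi - lo), class = "norm_record")
  list(unfiltered = apply_norm(unfiltered, rec),
       filtered = apply_norm(filtered, rec),
       record = rec)
}

#' Normalize a single volume to [0, 1]
#'
#' @param vol a [pet_volume()].
#' @return List: `vol` (normalized), `record` (`norm_record`).
#' @export
normalize_volume <- function(vol) {
  stopifnot(is_pet_volume(vol))
  lo <- min(vol$data); hi <- max(vol$data)
  if (hi <= lo)
    stop("degenerate normalization: constant volume", call. = FALSE)
  rec <- structure(list(offset = lo, scale = hi - lo), class = "norm_record")
  list(vol = apply_norm(vol, rec), record = rec)
}

apply_norm <- function(vol, rec) {
  pet_volume((vol$data - rec$offset) / rec$scale,
             spacing = vol$spacing, origin = vol$origin)
}

#' Invert a [0, 1] normalization
#'
#' @param vol a normalized [pet_volume()] (or plain array).
#' @param record the `norm_record` returned by [normalize_pair()] /
#'   [normalize_volume()].
#' @return The volume back on the SUV scale.
#' @export
invert_norm <- function(vol, record) {
  stopifnot(inherits(record, "norm_record"))
  if (is_pet_volume(vol))
    pet_volume(vol$data * record$scale + record$offset,
               spacing = vol$spacing, origin = vol$origin)
  else vol * record$scale + record$offset
}

#' Patch corner lattice with minimum-overlap guarantee
#'
#' 0-based corners on a regular lattice with per-axis stride
#' `floor(size * (1 - min_overlap_frac))` (24 voxels for 32-voxel patches
#' at 25% overlap), with the final corner snapped so the last patch abuts
#' the volume boundary. Every voxel is covered by at least one patch and
#' adjacent patches overlap by at least `min_overlap_frac * size` voxels.
#'
#' @param n axis length in voxels (must be >= `size`).
#' @param size patch edge length (default 32).
#' @param min_overlap_frac minimum fractional overlap (default 0.25).
#' @return Integer vector of 0-based corners.
#' @export
patch_corners <- function(n, size = 32L, min_overlap_frac = 0.25) {
  if (n < size)
    stop("axis length ", n, " smaller than patch size ", size, call. = FALSE)
  stride <- max(1L, as.integer(floor(size * (1 - min_overlap_frac))))
  corners <- seq.int(0L, n - size, by = stride)
  if (corners[length(corners)] != n - size)
    corners <- c(corners, n - size)
  as.integer(corners)
}

#' Extract co-located patch pairs from a normalized volume pair
#'
#' @param unfiltered,filtered congruent normalized [pet_volume()] objects
#'   (values in [0, 1]).
#' @param size cubic patch edge length (default 32).
#' @param min_overlap_frac minimum fractional overlap between adjacent
#'   patches (default 0.25).
#' @return List of `patch_pair` objects: `input`, `target` (3D arrays),
#'   `corner` (0-based voxel index of the patch origin).
#' @export
extract_patch_pairs <- function(unfiltered, filtered, size = 32L,
                                min_overlap_frac = 0.25) {
  stopifnot(is_pet_volume(unfiltered), is_pet_volume(filtered),
            identical(dim(unfiltered$data), dim(filtered$data)))
  d <- dim(unfiltered$data)
  cs <- lapply(1:3, function(a) patch_corners(d[a], size, min_overlap_frac))
  out <- list()
  for (cz in cs[[3]]) for (cy in cs[[2]]) for (cx in cs[[1]]) {
    ix <- (cx + 1):(cx + size); iy <- (cy + 1):(cy + size)
    iz <- (cz + 1):(cz + size)
    out[[length(out) + 1L]] <- structure(
      list(input = unfiltered$data[ix, iy, iz],
           target = filtered$data[ix, iy, iz],
           corner = c(cx, cy, cz)),
      class = "patch_pair")
  }
  out
}

#' Gamma-correction exponent from a Gaussian draw
#'
#' `gamma = (1 + |G|)^sign(G)` with `G ~ N(0, 0.5)`; `sign(0)` is taken
#' as 0 so `G = 0` gives exactly `gamma = 1`. The construction makes
#' `log(gamma)` symmetric about 0, so brightening and darkening
#' augmentations are balanced.
#'
#' @param g the Gaussian draw (scalar or vector).
#' @return Gamma exponent(s), always > 0.
#' @export
gamma_value <- function(g) {
  stopifnot(all(is.finite(g)))
  (1 + abs(g))^sign(g)
}

#' Run-time augmentation of a patch pair
#'
#' Independent 50% flips along each of the three axes and one shared
#' gamma correction `v -> v^gamma` ([gamma_value()] with
#' `G ~ N(0, 0.5)`), applied identically to input and target so the
#' input/target correspondence is preserved. Values stay in [0, 1] and
#' {0, 1} are fixed points of the gamma map. Deterministic given `seed`;
#' the caller's RNG state is untouched.
#'
#' @param pair a `patch_pair`.
#' @param seed integer seed for this draw.
#' @return The augmented `patch_pair`.
#' @export
augment_pair <- function(pair, seed) {
  stopifnot(inherits(pair, "patch_pair"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  flips <- stats::runif(3) < 0.5
  gam <- gamma_value(stats::rnorm(1, 0, 0.5))
  x <- pair$input; y <- pair$target
  for (ax in which(flips)) {
    idx <- rev(seq_len(dim(x)[ax]))
    if (ax == 1L) { x <- x[idx, , , drop = FALSE]; y <- y[idx, , , drop = FALSE] }
    if (ax == 2L) { x <- x[, idx, , drop = FALSE]; y <- y[, idx, , drop = FALSE] }
    if (ax == 3L) { x <- x[, , idx, drop = FALSE]; y <- y[, , idx, drop = FALSE] }
  }
  x <- x^gam; y <- y^gam
  structure(list(input = x, target = y, corner = pair$corner),
            class = "patch_pair")
}
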