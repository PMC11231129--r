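#' Denoise a whole PET volume with a trained network
#'
#' The volume is normalized to [0, 1] with its own [normalize_volume()]
#' record, processed in overlapping cubic tiles (the network is fully
#' convolutional, but bounded tiles keep memory flat), blended by uniform
#' averaging over tile overlaps, and mapped back to SUV. Axes shorter
#' than the tile are reflect-padded up to the tile size and cropped
#' afterwards. A zero-body network propagates the input unchanged (up to
#' the bypass clamp), seam-free across tiles.
#'
#' @param model a trained [build_model()] / [train_unet()] model.
#' @param vol a [pet_volume()] in SUV units.
#' @param tile cubic tile edge (default 64); must be divisible by
#'   `2^(depth-1)`.
#' @param overlap minimum tile overlap in voxels (default 16).
#' @return The denoised [pet_volume()], same geometry as the input.
#' @export
denoise_volume <- function(model, vol, tile = 64L, overlap = 16L) {
  stopifnot(inherits(model, "unet_model"), is_pet_volume(vol),
            overlap >= 0L, overlap < tile)
  div <- 2L^(model$spec$depth - 1L)
  if (tile %% div != 0L)
    stop("tile size must be divisible by ", div, " for depth ",
         model$spec$depth, call. = FALSE)
  nz <- normalize_volume(vol)
  x <- nz$vol$data
  d0 <- dim(x)
  # reflect-pad axes shorter than the tile
  pad <- pmax(tile - d0, 0L)
  if (any(pad > 0L)) x <- reflect_pad(x, pad)
  d <- dim(x)
  acc <- array(0, dim = d)
  cnt <- array(0, dim = d)
  cs <- lapply(1:3, function(a) tile_corners(d[a], tile, overlap))
  for (cz in cs[[3]]) for (cy in cs[[2]]) for (cx in cs[[1]]) {
    ix <- (cx + 1):(cx + tile); iy <- (cy + 1):(cy + tile)
    iz <- (cz + 1):(cz + tile)
    out <- unet_forward(model, x[ix, iy, iz])$out
    acc[ix, iy, iz] <- acc[ix, iy, iz] + out
    cnt[ix, iy, iz] <- cnt[ix, iy, iz] + 1
  }
  y <- acc / cnt
  y <- y[seq_len(d0[1]), seq_len(d0[2]), seq_len(d0[3]), drop = FALSE]
  dim(y) <- d0
  invert_norm(pet_volume(y, spacing = vol$spacing, origin = vol$origin),
              nz$record)
}

tile_corners <- function(n, tile, overlap) {
  if (n == tile) return(0L)
  stride <- max(1L, tile - overlap)
  corners <- seq.int(0L, n - tile, by = stride)
  if (corners[length(corners)] != n - tile)
    corners <- c(corners, n - tile)
  as.integer(corners)
}

reflect_pad <- function(x, pad) {
  for (ax in 1:3) {
    if (pad[ax] == 0L) next
    d <- dim(x)
    n <- d[ax]
    # reflect without repeating the edge sample; cycles for very short axes
    period <- c(seq_len(n), if (n > 2L) (n - 1L):2L)
    idx <- rep_len(period, n + pad[ax])
    if (ax == 1L) x <- x[idx, , , drop = FALSE]
    if (ax == 2L) x <- x[, idx, , drop = FALSE]
    if (ax == 3L) x <- x[, , idx, drop = FALSE]
  }
  x
}
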