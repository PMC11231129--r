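#' PET volume container
#'
#' A `pet_volume` wraps a 3D array of SUV values (g/mL) together with its
#' voxel spacing in mm and the physical position of voxel `(1,1,1)`.
#' Axes 1 and 2 are transaxial (x, y), axis 3 is axial (z). Dose/weight
#' decay correction is assumed to have been applied upstream: stored
#' intensities are treated as SUV throughout the package.
#'
#' @param data 3D numeric array of SUV values.
#' @param spacing numeric length-3, voxel size in mm per axis; strictly
#'   positive.
#' @param origin numeric length-3, physical position (mm) of the first
#'   voxel. The physical position of 0-based voxel index `v` is
#'   `origin + v * spacing` (axis-aligned grids only).
#' @return An object of class `pet_volume`.
#' @export
pet_volume <- function(data, spacing = c(3.3, 3.3, 2.0), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive finite values (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite values (mm)", call. = FALSE)
  if (any(dim(data) < 1L))
    stop("volume dimensions must be >= 1 on every axis", call. = FALSE)
  if (any(!is.finite(data)))
    stop("volume contains non-finite values", call. = FALSE)
  storage.mode(data) <- "double"
  if (any(data < 0))
    warning("volume contains negative SUV values", call. = FALSE)
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "pet_volume")
}

#' @export
print.pet_volume <- function(x, ...) {
  cat(sprintf("<pet_volume> %s voxels, spacing %s mm, SUV range [%.3g, %.3g]\n",
              paste(dim(x$data), collapse = " x "),
              paste(format(x$spacing, digits = 3), collapse = " x "),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.pet_volume <- function(x) dim(x$data)

is_pet_volume <- function(x) inherits(x, "pet_volume")

same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) <= tol * pmax(1, abs(a$spacing)))
}

#' Region-of-interest mask
#'
#' A boolean mask congruent with an associated [pet_volume()]. Roles follow
#' the study design used for filter-parameter selection: one `"liver"` mask
#' over a visually homogeneous liver area for noise assessment and a set of
#' `"lesion"` masks over focal uptake.
#'
#' @param mask 3D logical (or coercible) array; at least one voxel set.
#' @param role `"liver"` or `"lesion"`.
#' @param label free-text identifier.
#' @param ref optional `pet_volume`; when given, shape congruence is enforced.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(mask, role = c("lesion", "liver"), label = role, ref = NULL) {
  role <- match.arg(role)
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("`mask` must be a 3D array", call. = FALSE)
  mask <- array(as.logical(mask), dim = dim(mask))
  if (anyNA(mask)) stop("mask contains NA", call. = FALSE)
  if (!any(mask)) stop("empty ROI mask rejected", call. = FALSE)
  if (!is.null(ref) && !identical(dim(mask), dim(ref$data)))
    stop("ROI mask shape does not match reference volume", call. = FALSE)
  structure(list(mask = mask, role = role, label = label), class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> '%s' (%s), %d voxels set\n",
              x$label, x$role, sum(x$mask)))
  invisible(x)
}

#' ROI set for one study
#'
#' Exactly one liver mask plus at least one lesion mask, all congruent with
#' the study geometry.
#'
#' @param liver a `roi_mask` with role `"liver"`.
#' @param lesions list of `roi_mask` objects with role `"lesion"`.
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(liver, lesions) {
  if (!inherits(liver, "roi_mask") || liver$role != "liver")
    stop("`liver` must be a roi_mask with role 'liver'", call. = FALSE)
  if (inherits(lesions, "roi_mask")) lesions <- list(lesions)
  if (length(lesions) < 1L ||
      !all(vapply(lesions, function(m) inherits(m, "roi_mask") && m$role == "lesion", TRUE)))
    stop("`lesions` must be >= 1 roi_mask objects with role 'lesion'", call. = FALSE)
  shp <- dim(liver$mask)
  for (m in lesions)
    if (!identical(dim(m$mask), shp))
      stop("lesion mask shape differs from liver mask", call. = FALSE)
  structure(list(liver = liver, lesions = lesions), class = "roi_set")
}

#' Respiratory-gated study
#'
#' An ordered set of per-gate volumes plus the ungated reference volume.
#' All volumes must share shape and spacing. Clinical phase-based gating
#' typically yields 8 gates of similar noise characteristics; each gate
#' carries roughly `1/g` of the counts and is therefore noisier than the
#' ungated image by about `sqrt(g)`.
#'
#' @param gates list of `pet_volume`, one per respiratory gate, in phase order.
#' @param ungated `pet_volume`, the ungated (all-counts) image on the same grid.
#' @param tracer free-text tracer label.
#' @return An object of class `gated_study`.
#' @export
gated_study <- function(gates, ungated, tracer = "unknown") {
  if (is_pet_volume(gates)) gates <- list(gates)
  if (length(gates) < 1L || !all(vapply(gates, is_pet_volume, TRUE)))
    stop("`gates` must be a non-empty list of pet_volume objects", call. = FALSE)
  if (!is_pet_volume(ungated))
    stop("`ungated` must be a pet_volume", call. = FALSE)
  for (g in gates)
    if (!same_geometry(g, ungated))
      stop("all gates and the ungated volume must share shape and spacing",
           call. = FALSE)
  structure(list(gates = gates, ungated = ungated,
                 gate_count = length(gates), tracer = tracer),
            class = "gated_study")
}

#' @export
print.gated_study <- function(x, ...) {
  cat(sprintf("<gated_study> %d gates + ungated, %s voxels, tracer '%s'\n",
              x$gate_count, paste(dim(x$ungated$data), collapse = " x "),
              x$tracer))
  invisible(x)
}

#' Read a PET volume from a NIfTI-1 file
#'
#' Voxel spacing is taken from the header `pixdim` (mm); intensities are
#' passed through unchanged. Only 3D scalar payloads on axis-aligned grids
#' are accepted.
#'
#' @param path path to a `.nii`/`.nii.gz` file.
#' @return A [pet_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img2 <- array(as.numeric(img), dim = d[1:3])
    sp <- RNifti::pixdim(img)[1:3]
    return(pet_volume(img2, spacing = sp, origin = nifti_origin(img)))
  }
  if (length(d) != 3L)
    stop("expected a 3D scalar NIfTI payload, got ", length(d), "D: ", path,
         call. = FALSE)
  check_axis_aligned(img)
  pet_volume(array(as.numeric(img), dim = d),
             spacing = RNifti::pixdim(img)[1:3],
             origin = nifti_origin(img))
}

nifti_origin <- function(img) {
  x <- RNifti::xform(img)
  if (is.matrix(x) && all(dim(x) == c(4L, 4L))) as.numeric(x[1:3, 4]) else c(0, 0, 0)
}

check_axis_aligned <- function(img) {
  x <- try(RNifti::xform(img), silent = TRUE)
  if (inherits(x, "try-error") || !is.matrix(x)) return(invisible(TRUE))
  r <- x[1:3, 1:3]
  # exactly one nonzero entry per row/column = axis-aligned (allowing sign flips)
  ok <- all(rowSums(abs(r) > 1e-6) == 1L) && all(colSums(abs(r) > 1e-6) == 1L)
  if (!ok) stop("oblique (non-axis-aligned) orientation not supported", call. = FALSE)
  invisible(TRUE)
}

#' Write a PET volume to a NIfTI-1 file
#'
#' The written file round-trips: re-reading reproduces the data
#' bit-identically and the spacing within header precision.
#'
#' @param vol a [pet_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  if (!is_pet_volume(vol) || !is.array(vol$data) ||
      length(dim(vol$data)) != 3L)
    stop("`vol` must be a pet_volume with a 3D data array", call. = FALSE)
  if (any(!is.finite(vol$data)))
    stop("refusing to write non-finite voxel values", call. = FALSE)
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read an ROI mask from a NIfTI-1 file
#'
#' Nonzero voxels become `TRUE`. The mask grid must match the reference
#' volume; all-zero masks are rejected.
#'
#' @param path path to a NIfTI file with integer/boolean payload.
#' @param ref the associated [pet_volume()].
#' @param role,label passed to [roi_mask()].
#' @return A [roi_mask()].
#' @export
read_mask <- function(path, ref, role = c("lesion", "liver"), label = basename(path)) {
  role <- match.arg(role)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D mask payload: ", path, call. = FALSE)
  if (!identical(as.integer(d), as.integer(dim(ref$data))))
    stop("mask grid ", paste(d, collapse = "x"),
         " does not match reference grid ",
         paste(dim(ref$data), collapse = "x"), call. = FALSE)
  roi_mask(array(as.numeric(img) != 0, dim = d), role = role, label = label,
           ref = ref)
}

#' Write an ROI mask to a NIfTI-1 file
#'
#' @param mask a [roi_mask()].
#' @param path output path.
#' @param spacing voxel spacing (mm) recorded in the header.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, spacing = c(3.3, 3.3, 2.0)) {
  img <- RNifti::asNifti(array(as.integer(mask$mask), dim = dim(mask$mask)))
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}
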