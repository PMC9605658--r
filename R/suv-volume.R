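#' SUV volume objects
#'
#' An `suv_volume` is a 3D scalar field of standardized uptake values (SUV,
#' conventionally g/mL) on a regular grid, with voxel spacing and origin in
#' millimetres. Axis order is (x, y, z): array dimension 1 is x. The centre of
#' voxel `(i, j, k)` sits at `origin + (c(i, j, k) - 1) * spacing`. All
#' segmentation, metric extraction and phantom code in the package shares this
#' grid convention; masks are plain logical arrays congruent with the source
#' volume, so no resampling ever happens.
#'
#' @param values numeric 3D array of SUV values; must be finite and >= 0
#'   (negatives within `neg_tol` are clamped to zero).
#' @param spacing numeric(3), voxel spacing in mm per axis (all > 0).
#' @param origin numeric(3), world coordinate (mm) of the centre of voxel
#'   (1,1,1). Defaults to `spacing / 2` so the grid occupies
#'   `[0, dim * spacing]`.
#' @param neg_tol small negative values (>= `-neg_tol`) are clamped to 0, as
#'   can arise from float round-trips; more negative values are an error.
#' @return an object of class `suv_volume`: a list with elements `values`,
#'   `spacing`, `origin`.
#' @examples
#' vol <- suv_volume(array(1, c(4, 4, 4)), spacing = c(4, 4, 4))
#' voxel_volume_ml(vol) # 0.064
#' @export
suv_volume <- function(values, spacing, origin = spacing / 2, neg_tol = 0.01) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3D array, got ", length(dim(values)), " dims")
  if (anyNA(values))
    stop("SUV volume contains NaN/NA voxels")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 positive finite values (mm)")
  vmin <- min(values)
  if (vmin < -neg_tol)
    stop("SUV volume contains negative values below tolerance (min = ",
         signif(vmin, 4), ")")
  if (vmin < 0) {
    n_neg <- sum(values < 0)
    values[values < 0] <- 0
    message("clamped ", n_neg, " slightly negative voxel(s) to 0")
  }
  structure(
    list(values = values, spacing = spacing, origin = as.numeric(origin)),
    class = "suv_volume"
  )
}

#' @rdname suv_volume
#' @param x an `suv_volume`.
#' @export
voxel_volume_ml <- function(x) {
  stopifnot(inherits(x, "suv_volume"))
  prod(x$spacing) / 1000
}

#' @export
print.suv_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<suv_volume> %d x %d x %d voxels, spacing %s mm, SUV range [%.3g, %.3g]\n",
    d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x "),
    min(x$values), max(x$values)))
  invisible(x)
}

#' World coordinates of voxel centres along each axis
#' @noRd
axis_coords <- function(vol) {
  d <- dim(vol$values)
  lapply(1:3, function(a) vol$origin[a] + (seq_len(d[a]) - 1) * vol$spacing[a])
}

#' Read an SUV volume from a NIfTI-1 file
#'
#' Loads a 3D scalar NIfTI image (.nii or .nii.gz) and returns an
#' [suv_volume]. Spacing is taken from the header `pixdim`; the origin follows
#' the package grid convention (voxel (1,1,1) centred at `spacing/2`). NaN
#' voxels are an error; small negative values are clamped to zero with a
#' message.
#'
#' @param path path to a NIfTI-1 file.
#' @return an [suv_volume].
#' @export
load_suv_volume <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("'", path, "' is not a 3D scalar volume (", length(d), "D data)")
  sp <- RNifti::pixdim(img)
  if (length(sp) < 3L || any(!is.finite(sp[1:3])) || any(sp[1:3] <= 0))
    stop("'", path, "' has missing or invalid voxel spacing in its header")
  vals <- array(as.numeric(img), dim = d) # strip NIfTI attributes
  if (anyNA(vals))
    stop("'", path, "' contains NaN voxels")
  suv_volume(vals, spacing = as.numeric(sp[1:3]))
}

#' Write an SUV volume (or mask) as NIfTI-1
#'
#' @param vol an [suv_volume], or a logical/integer 3D array (written as uint8)
#'   together with `spacing`.
#' @param path output path (`.nii` for byte-reproducible output, `.nii.gz`
#'   also accepted).
#' @param spacing required when `vol` is a bare array.
#' @return `path`, invisibly.
#' @export
save_suv_volume <- function(vol, path, spacing = NULL) {
  if (inherits(vol, "suv_volume")) {
    arr <- vol$values
    sp <- vol$spacing
    dt <- "float"
  } else {
    if (is.null(spacing)) stop("'spacing' required when writing a bare array")
    arr <- array(as.integer(vol), dim = dim(vol))
    sp <- spacing
    dt <- "uint8"
  }
  attr(arr, "pixdim") <- sp
  img <- RNifti::asNifti(arr, datatype = dt)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Volumes of interest (VOIs)
#'
#' A VOI selects a set of voxels of an [suv_volume] by geometry in world
#' millimetres: a sphere (`center`, `radius`), an axis-aligned box (`center`,
#' `half_extent`), or an explicit logical mask congruent with the grid. A
#' voxel belongs to the VOI when its *centre* lies inside the geometry, the
#' same convention the phantom generator uses for lesion membership, so MTV
#' and reference means stay mutually consistent.
#'
#' @param center numeric(3), mm.
#' @param radius sphere radius, mm.
#' @param half_extent numeric(3), box half-widths, mm.
#' @param mask logical 3D array.
#' @param label free-text label (does not affect any computation).
#' @return an object of class `voi`.
#' @export
voi_sphere <- function(center, radius, label = "") {
  stopifnot(length(center) == 3L, radius > 0)
  structure(list(kind = "sphere", center = as.numeric(center),
                 radius = as.numeric(radius), label = label), class = "voi")
}

#' @rdname voi_sphere
#' @export
voi_box <- function(center, half_extent, label = "") {
  stopifnot(length(center) == 3L, length(half_extent) == 3L,
            all(half_extent > 0))
  structure(list(kind = "box", center = as.numeric(center),
                 half_extent = as.numeric(half_extent), label = label),
            class = "voi")
}

#' @rdname voi_sphere
#' @export
voi_mask <- function(mask, label = "") {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  structure(list(kind = "mask", mask = (mask != 0), label = label),
            class = "voi")
}

#' Rasterize a VOI onto a volume's grid
#'
#' @param vol an [suv_volume].
#' @param voi a [voi_sphere], [voi_box] or [voi_mask].
#' @return logical array congruent with `vol$values`.
#' @export
voi_to_mask <- function(vol, voi) {
  stopifnot(inherits(vol, "suv_volume"), inherits(voi, "voi"))
  d <- dim(vol$values)
  if (voi$kind == "mask") {
    if (!identical(dim(voi$mask), d))
      stop("explicit-mask VOI is not congruent with the volume grid")
    return(voi$mask)
  }
  co <- axis_coords(vol)
  if (voi$kind == "sphere") {
    dx2 <- (co[[1]] - voi$center[1])^2
    dy2 <- (co[[2]] - voi$center[2])^2
    dz2 <- (co[[3]] - voi$center[3])^2
    outer(outer(dx2, dy2, "+"), dz2, "+") <= voi$radius^2
  } else { # box
    inx <- abs(co[[1]] - voi$center[1]) <= voi$half_extent[1]
    iny <- abs(co[[2]] - voi$center[2]) <= voi$half_extent[2]
    inz <- abs(co[[3]] - voi$center[3]) <= voi$half_extent[3]
    outer(outer(inx, iny, "&"), inz, "&")
  }
}

#' Mean SUV over a reference VOI
#'
#' Arithmetic mean of the SUV values of all voxels whose centres lie in the
#' VOI. Used for the liver reference (the `I(background)` term of the adaptive
#' threshold and the denominator of the liver-ratio eligibility rule) and for
#' the mediastinal blood pool in Deauville scoring.
#'
#' @inheritParams voi_to_mask
#' @return scalar SUV.
#' @export
reference_mean <- function(vol, voi) {
  m <- voi_to_mask(vol, voi)
  if (!any(m))
    stop("VOI '", voi$label, "' does not intersect the volume grid")
  mean(vol$values[m])
}

#' Lesion query: operator initialization of one lymphoma site
#'
#' Semi-automatic delineation starts from operator input: a seed voxel inside
#' the lesion and a search VOI bounding the site. All four threshold methods
#' compute their lesion SUVmax within the search VOI and grow a connected
#' component from the seed, never leaking outside the VOI (adjacent nodal
#' sites stay separate).
#'
#' @param seed integer(3) voxel index (x, y, z) of a locally maximal voxel.
#' @param search_voi a [voi_sphere]/[voi_box]/[voi_mask] bounding the site.
#' @param label lesion label.
#' @return an object of class `lesion_query`.
#' @export
lesion_query <- function(seed, search_voi, label = "") {
  stopifnot(length(seed) == 3L, inherits(search_voi, "voi"))
  structure(list(seed = as.integer(seed), search_voi = search_voi,
                 label = label), class = "lesion_query")
}

#' Place the seed of a query at the hottest voxel of the search VOI
#'
#' Convenience used by the pipeline: given only a search VOI, returns a
#' [lesion_query] seeded at the voxel with maximal SUV inside it (ties broken
#' by lowest linear index).
#' @inheritParams voi_to_mask
#' @param search_voi the bounding VOI.
#' @param label lesion label.
#' @export
query_from_voi <- function(vol, search_voi, label = "") {
  m <- voi_to_mask(vol, search_voi)
  if (!any(m)) stop("search VOI '", label, "' does not intersect the grid")
  v <- vol$values
  v[!m] <- -Inf
  idx <- which.max(v) # first (lowest linear index) maximum
  lesion_query(arrayInd(idx, dim(v))[1, ], search_voi, label = label)
}

#' Write / read a VOI as a JSON sidecar
#' @param voi a `voi`.
#' @param path JSON path.
#' @export
save_voi <- function(voi, path) {
  stopifnot(inherits(voi, "voi"))
  if (voi$kind == "mask")
    stop("explicit-mask VOIs are stored as NIfTI masks, not JSON")
  jsonlite::write_json(unclass(voi), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_voi
#' @export
load_voi <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(x$kind, "sphere"))
    voi_sphere(x$center, x$radius, label = x$label %||% "")
  else if (identical(x$kind, "box"))
    voi_box(x$center, x$half_extent, label = x$label %||% "")
  else stop("unknown VOI kind in '", path, "'")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
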