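#' Lesion specification for digital phantoms
#'
#' Describes one synthetic lymphoma lesion as a sphere or ellipsoid of
#' elevated uptake. `uptake` is the peak tissue SUV before point-spread blur.
#' A nonzero `heterogeneity_amp` turns the uniform lesion into a radially
#' graded one: SUV falls linearly from `uptake` at the centre to
#' `uptake - heterogeneity_amp` at the rim. Graded lesions are what drives the
#' divergence between the relative 41%-of-SUVmax contour and the absolute
#' thresholds, because the relative threshold tracks the (high) centre value
#' while the absolute ones do not.
#'
#' @param center numeric(3), lesion centre in mm.
#' @param radius sphere radius in mm, or numeric(3) ellipsoid semi-axes.
#' @param uptake peak SUV (> 0).
#' @param heterogeneity_amp SUV drop from centre to rim; `0` = uniform;
#'   must be `>= 0` and `< uptake`.
#' @param label lesion label.
#' @return an object of class `lesion_spec`.
#' @export
lesion_spec <- function(center, radius, uptake, heterogeneity_amp = 0,
                        label = "") {
  radius <- as.numeric(radius)
  if (length(radius) == 1L) radius <- rep(radius, 3L)
  stopifnot(length(center) == 3L, length(radius) == 3L)
  if (any(radius <= 0)) stop("lesion radius must be > 0")
  if (uptake <= 0) stop("lesion uptake must be > 0")
  if (heterogeneity_amp < 0 || heterogeneity_amp >= uptake)
    stop("heterogeneity_amp must be in [0, uptake)")
  structure(list(center = as.numeric(center), radius = radius,
                 uptake = as.numeric(uptake),
                 heterogeneity_amp = as.numeric(heterogeneity_amp),
                 label = label), class = "lesion_spec")
}

#' Phantom specification
#'
#' Full description of one synthetic PET scan: grid geometry, a uniform
#' background, a liver region and a mediastinal blood-pool region of known
#' mean SUV, a list of lesions, an isotropic Gaussian point-spread function
#' (FWHM in mm) and additive Gaussian noise (clipped at zero so SUV stays
#' non-negative). The physiological ordering
#' `liver_suv > mediastinum_suv > background_suv > 0` is enforced, as is
#' pairwise disjointness of liver, mediastinum and lesion regions.
#'
#' @param grid_shape integer(3), voxels per axis.
#' @param voxel_spacing numeric(3) or scalar, mm per axis.
#' @param background_suv uniform background SUV.
#' @param liver_region,mediastinum_region a [voi_sphere] or [voi_box].
#' @param liver_suv,mediastinum_suv region mean SUV before blur/noise.
#' @param lesions list of [lesion_spec].
#' @param psf_fwhm full width at half maximum of the isotropic Gaussian PSF,
#'   mm (0 = no blur).
#' @param noise_sigma SD of additive Gaussian noise, SUV (0 = noiseless).
#' @param rng_seed integer seed for the noise stream.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape, voxel_spacing, background_suv,
                         liver_region, liver_suv,
                         mediastinum_region, mediastinum_suv,
                         lesions = list(), psf_fwhm = 0, noise_sigma = 0,
                         rng_seed = 1L) {
  voxel_spacing <- as.numeric(voxel_spacing)
  if (length(voxel_spacing) == 1L) voxel_spacing <- rep(voxel_spacing, 3L)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1),
            all(voxel_spacing > 0))
  if (!(liver_suv > mediastinum_suv && mediastinum_suv > background_suv &&
        background_suv > 0))
    stop("physiological ordering violated: need liver_suv > mediastinum_suv",
         " > background_suv > 0")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (psf_fwhm < 0) stop("psf_fwhm must be >= 0")
  lesions <- lapply(lesions, function(l) {
    if (!inherits(l, "lesion_spec")) stop("'lesions' must be lesion_spec objects")
    l
  })
  spec <- structure(
    list(grid_shape = as.integer(grid_shape), voxel_spacing = voxel_spacing,
         background_suv = background_suv,
         liver_region = liver_region, liver_suv = liver_suv,
         mediastinum_region = mediastinum_region,
         mediastinum_suv = mediastinum_suv,
         lesions = lesions, psf_fwhm = psf_fwhm, noise_sigma = noise_sigma,
         rng_seed = as.integer(rng_seed)),
    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

# Region bookkeeping: every named region must lie inside the grid and the
# liver / mediastinum / lesion supports must be pairwise disjoint.
validate_phantom_spec <- function(spec) {
  shell <- suv_volume(array(1, spec$grid_shape), spec$voxel_spacing)
  extent <- spec$grid_shape * spec$voxel_spacing
  regions <- c(
    list(liver = spec$liver_region, mediastinum = spec$mediastinum_region),
    stats::setNames(
      lapply(seq_along(spec$lesions), function(i) {
        l <- spec$lesions[[i]]
        voi_sphere(l$center, max(l$radius))
      }),
      vapply(seq_along(spec$lesions), function(i) {
        lb <- spec$lesions[[i]]$label
        if (nzchar(lb)) lb else paste0("lesion", i)
      }, character(1))
    ))
  masks <- lapply(names(regions), function(nm) {
    r <- regions[[nm]]
    lo <- r$center - if (r$kind == "sphere") r$radius else r$half_extent
    hi <- r$center + if (r$kind == "sphere") r$radius else r$half_extent
    if (any(lo < 0) || any(hi > extent))
      stop("region '", nm, "' extends outside the grid")
    voi_to_mask(shell, r)
  })
  names(masks) <- names(regions)
  nm <- names(masks)
  for (i in seq_along(masks)) for (j in seq_len(i - 1L)) {
    if (any(masks[[i]] & masks[[j]]))
      stop("regions '", nm[j], "' and '", nm[i], "' overlap")
  }
  invisible(masks)
}

# Separable Gaussian blur with edge replication; sigma in voxels per axis.
gaussian_blur <- function(arr, sigma_vox) {
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 0) next
    hw <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(seq(-hw, hw), sd = s)
    k <- k / sum(k)
    perm <- c(axis, setdiff(1:3, axis))
    a <- aperm(arr, perm)
    d <- dim(a)
    m <- matrix(a, nrow = d[1])
    m <- rbind(m[rep(1L, hw), , drop = FALSE], m,
               m[rep(nrow(m), hw), , drop = FALSE])
    f <- stats::filter(m, k, sides = 2)
    f <- f[(hw + 1L):(hw + d[1]), , drop = FALSE]
    a <- array(f, dim = d)
    arr <- aperm(a, order(perm))
  }
  arr
}

# Paint one lesion into the activity array; returns list(values, mask).
paint_lesion <- function(values, mask_out, coords, lesion) {
  dx <- (coords[[1]] - lesion$center[1]) / lesion$radius[1]
  dy <- (coords[[2]] - lesion$center[2]) / lesion$radius[2]
  dz <- (coords[[3]] - lesion$center[3]) / lesion$radius[3]
  r2 <- outer(outer(dx^2, dy^2, "+"), dz^2, "+")
  inside <- r2 <= 1
  if (lesion$heterogeneity_amp > 0) {
    val <- lesion$uptake - lesion$heterogeneity_amp * sqrt(pmin(r2, 1))
  } else {
    val <- array(lesion$uptake, dim = dim(r2))
  }
  values[inside] <- val[inside]
  mask_out[inside] <- TRUE
  list(values = values, mask = mask_out)
}

#' Generate a digital PET phantom
#'
#' Builds the noiseless activity map (background, liver, mediastinum,
#' lesions; a voxel belongs to a region when its centre is inside the analytic
#' shape), convolves it with the isotropic Gaussian PSF, adds Gaussian noise
#' clipped at zero, and returns the volume together with per-lesion ground
#' truth: the binary truth mask on the grid, the analytic volume in mL, the
#' voxelized volume in mL, and the true (pre-blur) mean and peak uptake.
#' Identical seeds give bit-identical volumes.
#'
#' @param spec a [phantom_spec].
#' @return list with elements `volume` (an [suv_volume]) and `ground_truth`
#'   (a list per lesion: `label`, `center`, `radius_mm`, `analytic_volume_ml`,
#'   `voxel_volume_ml`, `true_mean_uptake`, `true_peak_uptake`, `mask`), plus
#'   `liver_suv`, `mediastinum_suv`.
#' @examples
#' spec <- phantom_spec(
#'   grid_shape = c(40, 40, 40), voxel_spacing = 2, background_suv = 0.5,
#'   liver_region = voi_sphere(c(20, 20, 20), 8), liver_suv = 2,
#'   mediastinum_region = voi_sphere(c(60, 20, 20), 6), mediastinum_suv = 1.2,
#'   lesions = list(lesion_spec(c(40, 60, 55), radius = 10, uptake = 8)))
#' ph <- generate_phantom(spec)
#' max(ph$volume$values) # 8: no blur, no noise
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  d <- spec$grid_shape
  vol <- suv_volume(array(spec$background_suv, d), spec$voxel_spacing)
  coords <- axis_coords(vol)
  values <- vol$values
  values[voi_to_mask(vol, spec$liver_region)] <- spec$liver_suv
  values[voi_to_mask(vol, spec$mediastinum_region)] <- spec$mediastinum_suv

  gt <- vector("list", length(spec$lesions))
  for (i in seq_along(spec$lesions)) {
    les <- spec$lesions[[i]]
    empty <- array(FALSE, d)
    painted <- paint_lesion(values, empty, coords, les)
    values <- painted$values
    mask <- painted$mask
    gt[[i]] <- list(
      label = if (nzchar(les$label)) les$label else paste0("lesion", i),
      center = les$center, radius_mm = les$radius,
      analytic_volume_ml = 4 / 3 * pi * prod(les$radius) / 1000,
      voxel_volume_ml = sum(mask) * voxel_volume_ml(vol),
      true_mean_uptake = mean(values[mask]),
      true_peak_uptake = les$uptake,
      mask = mask)
  }

  if (spec$psf_fwhm > 0) {
    sigma_vox <- (spec$psf_fwhm / (2 * sqrt(2 * log(2)))) / spec$voxel_spacing
    values <- gaussian_blur(values, sigma_vox)
  }
  if (spec$noise_sigma > 0) {
    set.seed(spec$rng_seed)
    values <- values + stats::rnorm(length(values), 0, spec$noise_sigma)
    values[values < 0] <- 0
  }
  list(volume = suv_volume(array(values, d), spec$voxel_spacing),
       ground_truth = gt,
       liver_suv = spec$liver_suv, mediastinum_suv = spec$mediastinum_suv)
}
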