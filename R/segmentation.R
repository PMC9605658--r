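#' Connected component containing a seed voxel
#'
#' Breadth-first flood fill over a binary 3D grid under 26-connectivity
#' (voxels sharing a face, edge or corner are neighbours); 6-connectivity is
#' available for sensitivity analyses. If the seed voxel is not set, the
#' result is empty. The fill is layer-vectorized, so the result does not
#' depend on any visitation order.
#'
#' @param bin logical 3D array.
#' @param seed integer(3) voxel index.
#' @param connectivity 26 (default) or 6.
#' @return logical array of the same shape: the maximal connected set
#'   containing the seed.
#' @export
connected_component_from_seed <- function(bin, seed, connectivity = 26) {
  stopifnot(is.array(bin), length(dim(bin)) == 3L, length(seed) == 3L)
  d <- dim(bin)
  out <- array(FALSE, d)
  seed <- as.integer(seed)
  if (any(seed < 1L) || any(seed > d)) stop("seed outside the grid")
  if (!bin[seed[1], seed[2], seed[3]]) return(out)

  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(offs != 0) > 0, , drop = FALSE]
  if (connectivity == 6) {
    offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  } else if (connectivity != 26) stop("connectivity must be 6 or 26")

  out[seed[1], seed[2], seed[3]] <- TRUE
  frontier <- matrix(seed, nrow = 1)
  while (nrow(frontier) > 0L) {
    n <- nrow(frontier)
    m <- nrow(offs)
    cand <- frontier[rep(seq_len(n), each = m), , drop = FALSE] +
      offs[rep(seq_len(m), times = n), , drop = FALSE]
    ok <- cand[, 1] >= 1L & cand[, 1] <= d[1] &
          cand[, 2] >= 1L & cand[, 2] <= d[2] &
          cand[, 3] >= 1L & cand[, 3] <= d[3]
    cand <- cand[ok, , drop = FALSE]
    if (nrow(cand) == 0L) break
    lin <- cand[, 1] + d[1] * (cand[, 2] - 1L) + d[1] * d[2] * (cand[, 3] - 1L)
    keep <- !duplicated(lin)
    lin <- lin[keep]
    cand <- cand[keep, , drop = FALSE]
    new <- bin[lin] & !out[lin]
    if (!any(new)) break
    out[lin[new]] <- TRUE
    frontier <- cand[new, , drop = FALSE]
  }
  out
}

new_segmentation_result <- function(mask, method, applied_threshold,
                                    lesion_suvmax, query,
                                    liver_mean = NA_real_,
                                    isocontour_mean = NA_real_,
                                    eligible = TRUE, note = "") {
  structure(list(mask = mask, method = method,
                 applied_threshold = applied_threshold,
                 lesion_suvmax = lesion_suvmax,
                 liver_mean = liver_mean, isocontour_mean = isocontour_mean,
                 eligible = eligible, note = note,
                 label = query$label),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> method %s, threshold %.4g SUV, %d voxels%s\n",
              x$method, x$applied_threshold, sum(x$mask),
              if (nzchar(x$note)) paste0(" [", x$note, "]") else ""))
  invisible(x)
}

# Shared core: threshold inside the search VOI, keep the 26-connected
# component containing the seed. Inclusive comparison (SUV >= threshold).
segment_threshold_core <- function(vol, query, threshold, method,
                                   connectivity = 26, ...) {
  search <- voi_to_mask(vol, query$search_voi)
  s <- query$seed
  if (!search[s[1], s[2], s[3]])
    stop("seed voxel lies outside the search VOI for lesion '",
         query$label, "'")
  supra <- search & (vol$values >= threshold)
  suvmax <- max(vol$values[search])
  if (!supra[s[1], s[2], s[3]]) {
    warning("seed below threshold for lesion '", query$label,
            "' (", method, "): empty mask", call. = FALSE)
    return(new_segmentation_result(array(FALSE, dim(vol$values)), method,
                                   threshold, suvmax, query,
                                   note = "seed below threshold", ...))
  }
  mask <- connected_component_from_seed(supra, s, connectivity = connectivity)
  new_segmentation_result(mask, method, threshold, suvmax, query, ...)
}

lesion_suvmax_in_voi <- function(vol, query) {
  max(vol$values[voi_to_mask(vol, query$search_voi)])
}

#' Fixed 41%-of-SUVmax threshold (V41%)
#'
#' The lesion is delineated at 41% of its own SUVmax, where SUVmax is taken
#' within the search VOI (the "respective lymphoma site"), never globally.
#' The mask is the 26-connected supra-threshold component containing the
#' seed, restricted to the search VOI.
#'
#' @param vol an [suv_volume].
#' @param query a [lesion_query].
#' @param frac threshold fraction of SUVmax (0.41 by definition of the
#'   method; exposed for sensitivity analyses only).
#' @param connectivity passed to [connected_component_from_seed()].
#' @return a `segmentation_result`: `mask`, `method`, `applied_threshold`,
#'   `lesion_suvmax`, diagnostics.
#' @export
segment_v41 <- function(vol, query, frac = 0.41, connectivity = 26) {
  suvmax <- lesion_suvmax_in_voi(vol, query)
  if (suvmax <= 0) stop("SUVmax within the search VOI must be > 0")
  segment_threshold_core(vol, query, frac * suvmax, "v41",
                         connectivity = connectivity)
}

#' Fixed absolute SUV 2.5 threshold (V2.5)
#'
#' @inheritParams segment_v41
#' @param threshold absolute SUV cutoff (2.5 by definition of the method).
#' @return a `segmentation_result`.
#' @export
segment_v25 <- function(vol, query, threshold = 2.5, connectivity = 26) {
  segment_threshold_core(vol, query, threshold, "v25",
                         connectivity = connectivity)
}

#' Liver-referenced threshold (Vliver)
#'
#' A lesion is eligible only when its SUVmax exceeds 1.5 x the liver SUVmean
#' (the lesion-to-liver ratio rule); an ineligible site returns an empty mask
#' flagged `"below liver criterion"`, never an error — post-therapy residual
#' assessment depends on this. For eligible lesions the voxel threshold is,
#' by default, the same 1.5 x liver SUVmean; `rule = "eligibility_only"`
#' instead thresholds voxels at the liver SUVmean itself, keeping the ratio
#' purely as a positivity criterion.
#'
#' @inheritParams segment_v41
#' @param liver_mean liver reference SUVmean (> 0), from [reference_mean()].
#' @param ratio eligibility/threshold multiplier (1.5 by definition).
#' @param rule `"threshold"` (default) or `"eligibility_only"`.
#' @return a `segmentation_result` with `liver_mean` and `eligible` recorded.
#' @export
segment_vliver <- function(vol, query, liver_mean, ratio = 1.5,
                           rule = c("threshold", "eligibility_only"),
                           connectivity = 26) {
  rule <- match.arg(rule)
  if (liver_mean <= 0) stop("liver_mean must be > 0")
  suvmax <- lesion_suvmax_in_voi(vol, query)
  if (suvmax / liver_mean <= ratio) {
    return(new_segmentation_result(
      array(FALSE, dim(vol$values)), "vliver", ratio * liver_mean, suvmax,
      query, liver_mean = liver_mean, eligible = FALSE,
      note = "below liver criterion"))
  }
  thr <- if (rule == "threshold") ratio * liver_mean else liver_mean
  segment_threshold_core(vol, query, thr, "vliver",
                         connectivity = connectivity, liver_mean = liver_mean)
}

#' Adaptive background-corrected threshold (AM)
#'
#' Single-pass adaptive rule: let `Imax` be the lesion SUVmax within the
#' search VOI and `I(mean)` the mean SUV over the 70%-of-Imax isocontour
#' (the 26-connected component of voxels `>= 0.7 * Imax` containing the
#' seed, inside the search VOI). The applied threshold is
#' `0.15 * I(mean) + liver_mean`, with the liver SUVmean standing in for the
#' local background. If the computed threshold exceeds Imax the mask is
#' empty, with a warning.
#'
#' @inheritParams segment_vliver
#' @param iso_frac isocontour fraction of Imax (0.70 by definition).
#' @param slope multiplier on `I(mean)` (0.15 by definition).
#' @return a `segmentation_result` with `isocontour_mean` and `liver_mean`
#'   recorded in the diagnostics.
#' @export
segment_am <- function(vol, query, liver_mean, iso_frac = 0.70, slope = 0.15,
                       connectivity = 26) {
  if (liver_mean <= 0) stop("liver_mean must be > 0")
  search <- voi_to_mask(vol, query$search_voi)
  s <- query$seed
  if (!search[s[1], s[2], s[3]])
    stop("seed voxel lies outside the search VOI for lesion '",
         query$label, "'")
  imax <- max(vol$values[search])
  iso_bin <- search & (vol$values >= iso_frac * imax)
  iso_cc <- connected_component_from_seed(iso_bin, s,
                                          connectivity = connectivity)
  if (!any(iso_cc)) {
    # only possible when the seed itself is below 70% of Imax
    warning("seed below the 70% isocontour for lesion '", query$label,
            "': empty AM mask", call. = FALSE)
    return(new_segmentation_result(
      array(FALSE, dim(vol$values)), "am", NA_real_, imax, query,
      liver_mean = liver_mean, note = "seed below isocontour"))
  }
  imean <- mean(vol$values[iso_cc])
  thr <- slope * imean + liver_mean
  if (thr > imax) {
    warning("adaptive threshold ", signif(thr, 4), " exceeds lesion SUVmax ",
            signif(imax, 4), " for '", query$label, "': empty mask",
            call. = FALSE)
    return(new_segmentation_result(
      array(FALSE, dim(vol$values)), "am", thr, imax, query,
      liver_mean = liver_mean, isocontour_mean = imean,
      note = "threshold above SUVmax"))
  }
  segment_threshold_core(vol, query, thr, "am", connectivity = connectivity,
                         liver_mean = liver_mean, isocontour_mean = imean)
}

#' Run one of the four threshold methods by name
#'
#' @inheritParams segment_vliver
#' @param method one of `"v41"`, `"v25"`, `"vliver"`, `"am"`.
#' @param ... passed to the specific method.
#' @return a `segmentation_result`.
#' @export
segment_lesion <- function(vol, query, method, liver_mean = NULL, ...) {
  switch(method,
    v41 = segment_v41(vol, query, ...),
    v25 = segment_v25(vol, query, ...),
    vliver = segment_vliver(vol, query, liver_mean, ...),
    am = segment_am(vol, query, liver_mean, ...),
    stop("unknown segmentation method '", method, "'"))
}

#' All four segmentation methods
#' @export
SEGMENTATION_METHODS <- c("v41", "v25", "vliver", "am")
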