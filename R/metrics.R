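#' SUVpeak: mean uptake in a 1 mL sphere around the hottest voxel
#'
#' Finds the hottest voxel of the mask (ties broken by the tied voxel
#' nearest the mask centroid, then by lowest linear index — on a constant
#' lesion this centres the sphere in the lesion rather than on its edge)
#' and averages the SUV of all voxels whose centres lie within a sphere of
#' volume 1 mL (radius `(3/(4*pi))^(1/3)` cm, about 6.204 mm) centred on it.
#' The sphere is an image neighbourhood, not a mask statistic: it may include
#' voxels outside the mask. If it would extend beyond the grid it is clipped
#' to the in-grid portion, with a warning.
#'
#' @param vol an [suv_volume].
#' @param mask logical array congruent with `vol`.
#' @return scalar SUV; 0 for an empty mask.
#' @export
compute_suvpeak <- function(vol, mask) {
  stopifnot(inherits(vol, "suv_volume"))
  if (!identical(dim(mask), dim(vol$values)))
    stop("mask grid does not match the volume grid")
  if (!any(mask)) return(0)
  v <- vol$values
  vm <- v
  vm[!mask] <- -Inf
  mx <- max(vm)
  tied <- which(vm == mx)
  if (length(tied) > 1L) {
    # deterministic tie-break: tied voxel nearest the mask centroid
    ti <- arrayInd(tied, dim(v))
    ci <- arrayInd(which(mask), dim(v))
    centroid <- colMeans(ci)
    d2 <- rowSums((t(t(ti) - centroid) * rep(vol$spacing, each = nrow(ti)))^2)
    hot <- ti[order(d2, tied)[1], ]
  } else {
    hot <- arrayInd(tied, dim(v))[1, ]
  }
  r <- (3 / (4 * pi) * 1000)^(1 / 3) # mm, sphere of 1 mL
  center <- vol$origin + (hot - 1) * vol$spacing
  d <- dim(v)
  lo <- center - r
  hi <- center + r
  extent_lo <- vol$origin - vol$spacing / 2
  extent_hi <- vol$origin + (d - 0.5) * vol$spacing
  if (any(lo < extent_lo) || any(hi > extent_hi))
    warning("1 mL SUVpeak sphere clipped at the grid boundary", call. = FALSE)
  sph <- voi_to_mask(vol, voi_sphere(center, r))
  mean(v[sph])
}

#' Extract per-lesion semi-quantitative and volumetric metrics
#'
#' From a segmentation mask: SUVmax (hottest masked voxel), SUVmean (mask
#' mean), SUVpeak ([compute_suvpeak()]), MTV in mL (voxel count times voxel
#' volume) and TLG = MTV x SUVmean. An empty mask — a cleared, post-therapy
#' site — yields all-zero metrics, never an error.
#'
#' @param vol an [suv_volume].
#' @param seg a `segmentation_result` (or a bare logical mask).
#' @return an object of class `lesion_metrics`: list with `suvmax`,
#'   `suvmean`, `suvpeak`, `mtv_ml`, `tlg`, `method`, `label`.
#' @export
extract_metrics <- function(vol, seg) {
  if (inherits(seg, "segmentation_result")) {
    mask <- seg$mask; method <- seg$method; label <- seg$label
  } else {
    mask <- seg; method <- NA_character_; label <- ""
  }
  if (!identical(dim(mask), dim(vol$values)))
    stop("mask grid does not match the volume grid")
  if (!any(mask)) {
    out <- list(suvmax = 0, suvmean = 0, suvpeak = 0, mtv_ml = 0, tlg = 0,
                method = method, label = label)
    return(structure(out, class = "lesion_metrics"))
  }
  vals <- vol$values[mask]
  mtv <- sum(mask) * voxel_volume_ml(vol)
  suvmean <- mean(vals)
  structure(list(suvmax = max(vals), suvmean = suvmean,
                 suvpeak = compute_suvpeak(vol, mask),
                 mtv_ml = mtv, tlg = mtv * suvmean,
                 method = method, label = label),
            class = "lesion_metrics")
}

#' Aggregate per-lesion metrics into one per-scan record
#'
#' Multi-lesion totals follow the total-MTV convention: MTV and TLG are
#' summed over lesions, the scan SUVmean is the volume-weighted mean
#' (total TLG / total MTV), SUVmax is the maximum over lesions, and SUVpeak
#' is that of the hottest lesion. A scan with no residual lesions is valid
#' and has all totals zero.
#'
#' @param lesions list of `lesion_metrics`, all from the same method.
#' @param patient_id,timepoint scan labels.
#' @param liver_mean,mediastinum_mean measured reference SUVmeans.
#' @param deauville optional Deauville score (1-5) for the scan.
#' @return an object of class `scan_record` (a one-row data.frame with
#'   columns `patient_id`, `timepoint`, `method`, `suvmax`, `suvmean`,
#'   `suvpeak`, `mtv_ml`, `tlg`, `n_lesions`, `liver_mean`,
#'   `mediastinum_mean`, `ds`).
#' @export
aggregate_scan <- function(lesions, patient_id, timepoint,
                           liver_mean = NA_real_, mediastinum_mean = NA_real_,
                           deauville = NA_integer_) {
  methods <- unique(vapply(lesions, `[[`, character(1), "method"))
  if (length(methods) > 1L)
    stop("cannot aggregate lesions segmented with mixed methods: ",
         paste(methods, collapse = ", "))
  method <- if (length(methods)) methods else NA_character_
  mtv <- sum(vapply(lesions, `[[`, numeric(1), "mtv_ml"))
  tlg <- sum(vapply(lesions, `[[`, numeric(1), "tlg"))
  if (length(lesions) && mtv > 0) {
    suvmaxes <- vapply(lesions, `[[`, numeric(1), "suvmax")
    hottest <- which.max(suvmaxes)
    suvmax <- suvmaxes[hottest]
    suvpeak <- lesions[[hottest]]$suvpeak
    suvmean <- tlg / mtv
  } else {
    suvmax <- suvmean <- suvpeak <- 0
    mtv <- tlg <- 0
  }
  rec <- data.frame(patient_id = patient_id, timepoint = timepoint,
                    method = method, suvmax = suvmax, suvmean = suvmean,
                    suvpeak = suvpeak, mtv_ml = mtv, tlg = tlg,
                    n_lesions = length(lesions),
                    liver_mean = liver_mean,
                    mediastinum_mean = mediastinum_mean,
                    ds = as.integer(deauville),
                    stringsAsFactors = FALSE)
  class(rec) <- c("scan_record", class(rec))
  rec
}

#' Percentage change of a metric between two timepoints
#'
#' `100 * (followup - baseline) / baseline`: negative for a reduction, -100
#' for complete clearance. A zero baseline makes the change undefined and
#' returns `NA`, never 0 — those pairs are dropped listwise downstream.
#'
#' @param baseline,followup scalar metric values, or `scan_record`s together
#'   with `field`.
#' @param field column name when records are passed (e.g. `"mtv_ml"`).
#' @return percent change (scalar).
#' @export
percent_change <- function(baseline, followup, field = NULL) {
  if (!is.null(field)) {
    stopifnot(inherits(baseline, "scan_record"), inherits(followup, "scan_record"))
    if (baseline$patient_id != followup$patient_id ||
        !identical(baseline$method, followup$method))
      stop("percent_change requires the same patient and method")
    baseline <- baseline[[field]]
    followup <- followup[[field]]
  }
  if (!is.finite(baseline) || baseline == 0) return(NA_real_)
  100 * (followup - baseline) / baseline
}
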