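#' Cohort specification: a multi-timepoint synthetic PET study
#'
#' Describes a cohort of patients scanned at baseline (`PET1`), interim
#' (`PET2`) and end of chemotherapy (`PET3`). Each patient is a jittered copy
#' of a template phantom whose lesions then respond to therapy according to
#' `response_model`: multiplicative shrinkage of lesion uptake and radius at
#' PET2/PET3 (relative to PET1), plus a per-patient probability of complete
#' metabolic clearance. Cleared lesions are absent from the truth (and from
#' the image) at that and all later timepoints, so the per-patient Deauville
#' outcome is known by construction.
#'
#' @param n_patients number of patients.
#' @param timepoints ordered scan labels; must start with `"PET1"`.
#' @param response_model list with elements `pet2` and `pet3`, each a list
#'   `uptake_shrink = c(lo, hi)`, `radius_shrink = c(lo, hi)` (uniform ranges
#'   of multiplicative factors in `[0, 1]`, applied to the PET1 value) and
#'   `clear_prob` (probability of complete clearance by that timepoint).
#'   The drawn PET3 factors are capped at the PET2 factors so response is
#'   monotone over time.
#' @param baseline_jitter list `uptake = c(lo, hi)`, `radius = c(lo, hi)`:
#'   per-lesion multiplicative jitter applied at PET1 so patients differ.
#' @param rng_seed integer master seed; per-patient streams are derived at a
#'   fixed offset so generation is reproducible.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients,
                        timepoints = c("PET1", "PET2", "PET3"),
                        response_model = list(
                          pet2 = list(uptake_shrink = c(0.25, 0.70),
                                      radius_shrink = c(0.40, 0.80),
                                      clear_prob = 0.15),
                          pet3 = list(uptake_shrink = c(0.20, 0.60),
                                      radius_shrink = c(0.30, 0.70),
                                      clear_prob = 0.70)),
                        baseline_jitter = list(uptake = c(0.80, 1.30),
                                               radius = c(0.75, 1.25)),
                        rng_seed = 1L) {
  stopifnot(n_patients >= 1)
  if (timepoints[1] != "PET1")
    stop("timepoints must start with PET1 (the baseline)")
  for (tp in c("pet2", "pet3")) {
    rm_ <- response_model[[tp]]
    if (is.null(rm_)) next
    for (f in c("uptake_shrink", "radius_shrink")) {
      rng <- rm_[[f]]
      if (any(rng < 0) || any(rng > 1))
        stop("response_model$", tp, "$", f, " factors must lie in [0, 1]")
    }
    if (rm_$clear_prob < 0 || rm_$clear_prob > 1)
      stop("clear_prob must be a probability")
  }
  structure(list(n_patients = as.integer(n_patients), timepoints = timepoints,
                 response_model = response_model,
                 baseline_jitter = baseline_jitter,
                 rng_seed = as.integer(rng_seed)),
            class = "cohort_spec")
}

runif1 <- function(rng) stats::runif(1, rng[1], rng[2])

#' Generate a synthetic cohort of SUV volumes with ground truth
#'
#' For each patient: jitter the template lesions at PET1, draw the patient's
#' response factors once, then render one phantom per timepoint (shrunk or
#' cleared lesions at PET2/PET3). The true Deauville score of each follow-up
#' scan is derived from the known residual peak uptake against the template's
#' true mediastinum and liver SUV (clearance = DS 1).
#'
#' @param cohort a [cohort_spec].
#' @param template a [phantom_spec]; its lesions define the baseline sites.
#' @return list of scan records, each a list with `patient_id`, `timepoint`,
#'   `volume`, `ground_truth` (as in [generate_phantom]), `true_ds`
#'   (`NA` at PET1), `liver_suv`, `mediastinum_suv`, and
#'   `baseline_lesions` (the jittered PET1 [lesion_spec]s, identical across
#'   the patient's scans — the sites an operator would query).
#' @export
generate_cohort <- function(cohort, template) {
  stopifnot(inherits(cohort, "cohort_spec"), inherits(template, "phantom_spec"))
  scans <- list()
  for (p in seq_len(cohort$n_patients)) {
    set.seed(cohort$rng_seed + 1000L * p)
    base_lesions <- lapply(seq_along(template$lesions), function(i) {
      l <- template$lesions[[i]]
      um <- runif1(cohort$baseline_jitter$uptake)
      rm_ <- runif1(cohort$baseline_jitter$radius)
      lesion_spec(l$center, l$radius * rm_, l$uptake * um,
                  heterogeneity_amp = l$heterogeneity_amp * um,
                  label = if (nzchar(l$label)) l$label else paste0("lesion", i))
    })
    rm2 <- cohort$response_model$pet2
    rm3 <- cohort$response_model$pet3
    u2 <- runif1(rm2$uptake_shrink); r2 <- runif1(rm2$radius_shrink)
    u3 <- min(runif1(rm3$uptake_shrink), u2)
    r3 <- min(runif1(rm3$radius_shrink), r2)
    clear2 <- stats::runif(1) < rm2$clear_prob
    clear3 <- clear2 || stats::runif(1) < rm3$clear_prob
    factors <- list(PET1 = list(u = 1, r = 1, cleared = FALSE),
                    PET2 = list(u = u2, r = r2, cleared = clear2),
                    PET3 = list(u = u3, r = r3, cleared = clear3))

    for (ti in seq_along(cohort$timepoints)) {
      tp <- cohort$timepoints[ti]
      fac <- factors[[tp]]
      lesions_t <- if (fac$cleared) list() else lapply(base_lesions, function(l)
        lesion_spec(l$center, l$radius * fac$r, l$uptake * fac$u,
                    heterogeneity_amp = l$heterogeneity_amp * fac$u,
                    label = l$label))
      spec_t <- phantom_spec(
        grid_shape = template$grid_shape,
        voxel_spacing = template$voxel_spacing,
        background_suv = template$background_suv,
        liver_region = template$liver_region, liver_suv = template$liver_suv,
        mediastinum_region = template$mediastinum_region,
        mediastinum_suv = template$mediastinum_suv,
        lesions = lesions_t, psf_fwhm = template$psf_fwhm,
        noise_sigma = template$noise_sigma,
        rng_seed = cohort$rng_seed + 1000L * p + ti)
      ph <- generate_phantom(spec_t)
      true_ds <- if (tp == "PET1") NA_integer_ else {
        if (fac$cleared || length(lesions_t) == 0L) 1L else {
          peak <- max(vapply(lesions_t, `[[`, numeric(1), "uptake"))
          assign_deauville(peak, template$mediastinum_suv,
                           template$liver_suv)$ds
        }
      }
      scans[[length(scans) + 1L]] <- list(
        patient_id = sprintf("P%03d", p), timepoint = tp,
        volume = ph$volume, ground_truth = ph$ground_truth,
        true_ds = true_ds,
        liver_suv = template$liver_suv,
        mediastinum_suv = template$mediastinum_suv,
        baseline_lesions = base_lesions)
    }
  }
  scans
}

#' Default phantom template and cohort used throughout the package
#'
#' A 56 x 56 x 44 grid at 3 mm isotropic spacing (16.8 x 16.8 x 13.2 cm
#' field) holding a uniform background (SUV 0.7), a liver sphere (radius
#' 15 mm, SUV 2.0), a mediastinal blood-pool box (SUV 1.5) and two
#' radially-graded nodal lesions (radii 16 and 11 mm; peak SUV 9 and 7;
#' centre-to-rim drops 5 and 3). PSF FWHM 6 mm and additive noise SD 0.15 SUV
#' approximate clinically reconstructed pediatric FDG-PET.
#'
#' @param psf_fwhm,noise_sigma override the image-degradation defaults.
#' @param rng_seed seed for the noise stream.
#' @return a [phantom_spec].
#' @export
default_phantom_template <- function(psf_fwhm = 6, noise_sigma = 0.15,
                                     rng_seed = 1L) {
  phantom_spec(
    grid_shape = c(56, 56, 44), voxel_spacing = 3, background_suv = 0.7,
    liver_region = voi_sphere(c(120, 60, 40), 15, label = "liver"),
    liver_suv = 2.0,
    mediastinum_region = voi_box(c(84, 84, 66), c(12, 12, 15),
                                 label = "mediastinum"),
    mediastinum_suv = 1.5,
    lesions = list(
      lesion_spec(c(54, 126, 96), radius = 16, uptake = 9,
                  heterogeneity_amp = 5, label = "nodal_A"),
      lesion_spec(c(110, 120, 80), radius = 11, uptake = 7,
                  heterogeneity_amp = 3, label = "nodal_B")),
    psf_fwhm = psf_fwhm, noise_sigma = noise_sigma, rng_seed = rng_seed)
}

#' @rdname default_phantom_template
#' @param n_patients cohort size.
#' @export
default_cohort_spec <- function(n_patients = 20, rng_seed = 1L) {
  cohort_spec(n_patients = n_patients, rng_seed = rng_seed)
}

#' Reference VOIs matching the default template
#'
#' The liver reference is a 3 cm-diameter sphere concentric with the
#' template's liver region; the mediastinal reference is a sphere inside the
#' blood-pool box.
#' @return list with elements `liver` and `mediastinum` ([voi_sphere]s).
#' @export
default_reference_vois <- function() {
  list(liver = voi_sphere(c(120, 60, 40), 15, label = "liver"),
       mediastinum = voi_sphere(c(84, 84, 66), 9, label = "mediastinum"))
}

#' Write a cohort to disk as NIfTI volumes plus a manifest CSV
#'
#' @param scans output of [generate_cohort].
#' @param dir output directory (created if needed).
#' @param write_masks also write per-lesion truth masks (uint8 NIfTI).
#' @param compress write `.nii.gz` instead of `.nii`. The default is
#'   uncompressed so repeated runs are byte-identical.
#' @return data.frame manifest (also written to `dir/cohort_manifest.csv`).
#' @export
write_cohort <- function(scans, dir, write_masks = FALSE, compress = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (compress) ".nii.gz" else ".nii"
  rows <- lapply(scans, function(s) {
    fn <- paste0(s$patient_id, "_", s$timepoint, ext)
    save_suv_volume(s$volume, file.path(dir, fn))
    if (write_masks) for (g in s$ground_truth)
      save_suv_volume(g$mask,
                      file.path(dir, paste0(s$patient_id, "_", s$timepoint,
                                            "_", g$label, "_truth", ext)),
                      spacing = s$volume$spacing)
    n_les <- length(s$ground_truth)
    data.frame(patient_id = s$patient_id, timepoint = s$timepoint, path = fn,
               n_lesions = n_les,
               true_total_volume_ml = if (n_les) sum(vapply(
                 s$ground_truth, `[[`, numeric(1), "analytic_volume_ml")) else 0,
               true_ds = s$true_ds,
               liver_suv = s$liver_suv, mediastinum_suv = s$mediastinum_suv,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "cohort_manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
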