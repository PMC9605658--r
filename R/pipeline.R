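#' Run configuration for the end-to-end study
#'
#' Collects every knob of the simulate -> segment -> score -> compare
#' pipeline in one validated list. All stages hand data over as plain files
#' (NIfTI volumes and masks, CSV tables, JSON sidecars) so each stage can be
#' re-run and inspected in isolation, and a fixed `seed` makes the whole run
#' byte-reproducible.
#'
#' @param out_dir output directory.
#' @param n_patients cohort size.
#' @param seed global integer seed; all derived streams come from it.
#' @param methods subset of `v41`, `v25`, `vliver`, `am`.
#' @param search_margin_mm margin added to the baseline lesion radius to form
#'   each site's spherical search VOI.
#' @param gate_ratio follow-up positivity gate: a site is delineated on
#'   PET2/PET3 only if its search-VOI SUVmax exceeds `gate_ratio` x liver
#'   SUVmean (the same criterion as Vliver eligibility); below it all
#'   methods record an empty mask, as an operator would not contour an
#'   invisible site.
#' @param ds_reference_method method whose masks define residual uptake for
#'   Deauville scoring (DS is one per scan, method-independent).
#' @param ds5_factor,ds_outcome Deauville options (see [assign_deauville()],
#'   [dichotomize_deauville()]).
#' @param vliver_rule passed to [segment_vliver()].
#' @param loa_multiplier passed to [bland_altman()].
#' @param psf_fwhm,noise_sigma image degradation of the phantom template.
#' @param write_masks write every segmentation mask as uint8 NIfTI.
#' @param write_plots write scatter / Bland-Altman panels (PNG).
#' @return a named list of class `run_config`.
#' @export
run_config <- function(out_dir, n_patients = 20, seed = 1L,
                       methods = SEGMENTATION_METHODS,
                       search_margin_mm = 10, gate_ratio = 1.5,
                       ds_reference_method = "vliver", ds5_factor = 2.0,
                       ds_outcome = "at_most",
                       vliver_rule = "threshold", loa_multiplier = 1.96,
                       psf_fwhm = 6, noise_sigma = 0.15,
                       write_masks = FALSE, write_plots = TRUE) {
  bad <- setdiff(methods, SEGMENTATION_METHODS)
  if (length(bad))
    stop("unknown segmentation method(s): ", paste(bad, collapse = ", "))
  if (!ds_reference_method %in% methods)
    stop("ds_reference_method must be one of the configured methods")
  structure(list(out_dir = out_dir, n_patients = as.integer(n_patients),
                 seed = as.integer(seed), methods = methods,
                 search_margin_mm = search_margin_mm,
                 gate_ratio = gate_ratio,
                 ds_reference_method = ds_reference_method,
                 ds5_factor = ds5_factor, ds_outcome = ds_outcome,
                 vliver_rule = vliver_rule,
                 loa_multiplier = loa_multiplier,
                 psf_fwhm = psf_fwhm, noise_sigma = noise_sigma,
                 write_masks = write_masks, write_plots = write_plots),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file whose keys are `run_config()` arguments.
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (is.null(x$out_dir)) stop("config must set out_dir")
  do.call(run_config, x)
}

#' Build the lesion queries for one patient from the baseline lesion sites
#'
#' One spherical search VOI per baseline lesion (its true centre, radius
#' plus `margin_mm`); the seed is re-placed at the hottest voxel of the VOI
#' on each scan, which is how an operator re-uses baseline sites at
#' follow-up.
#'
#' @param vol the scan's [suv_volume].
#' @param baseline_lesions list of [lesion_spec]s at PET1.
#' @param margin_mm search margin.
#' @return list of [lesion_query].
#' @export
queries_for_scan <- function(vol, baseline_lesions, margin_mm = 10) {
  lapply(baseline_lesions, function(l)
    query_from_voi(vol, voi_sphere(l$center, max(l$radius) + margin_mm,
                                   label = l$label), label = l$label))
}

#' Segment one scan with several methods and aggregate its metrics
#'
#' Applies the follow-up positivity gate, runs each configured method at
#' each queried site, extracts lesion metrics and aggregates them into one
#' [aggregate_scan()] record per method.
#'
#' @param vol the scan's [suv_volume].
#' @param queries list of [lesion_query] (baseline sites).
#' @param liver_mean,mediastinum_mean measured reference SUVmeans.
#' @param patient_id,timepoint scan labels.
#' @param methods methods to run.
#' @param gate apply the positivity gate (`TRUE` on follow-up scans).
#' @param gate_ratio,vliver_rule see [run_config()].
#' @return list with `records` (one data.frame row-bound over methods) and
#'   `segmentations` (nested list `[[method]][[site]]`).
#' @export
segment_scan <- function(vol, queries, liver_mean, mediastinum_mean,
                         patient_id, timepoint,
                         methods = SEGMENTATION_METHODS, gate = FALSE,
                         gate_ratio = 1.5, vliver_rule = "threshold") {
  active <- vapply(queries, function(q) {
    !gate || lesion_suvmax_in_voi(vol, q) > gate_ratio * liver_mean
  }, logical(1))
  segs <- list()
  recs <- list()
  for (method in methods) {
    site_segs <- list()
    lesions <- list()
    for (i in seq_along(queries)) {
      if (!active[i]) next
      seg <- suppressWarnings(switch(method,
        v41 = segment_v41(vol, queries[[i]]),
        v25 = segment_v25(vol, queries[[i]]),
        vliver = segment_vliver(vol, queries[[i]], liver_mean,
                                rule = vliver_rule),
        am = segment_am(vol, queries[[i]], liver_mean)))
      site_segs[[queries[[i]]$label]] <- seg
      lesions[[length(lesions) + 1L]] <- extract_metrics(vol, seg)
    }
    # drop empty-mask lesions from the aggregate (they contribute zeros)
    lesions <- Filter(function(l) l$mtv_ml > 0, lesions)
    for (i in seq_along(lesions)) lesions[[i]]$method <- method
    segs[[method]] <- site_segs
    recs[[method]] <- aggregate_scan(lesions, patient_id, timepoint,
                                     liver_mean = liver_mean,
                                     mediastinum_mean = mediastinum_mean)
    recs[[method]]$method <- method
  }
  list(records = do.call(rbind, recs), segmentations = segs)
}

#' Run the full synthetic study end to end
#'
#' Simulates a cohort from the default phantom template, writes every
#' volume, segments each scan with the configured methods, extracts and
#' aggregates metrics, assigns Deauville scores from the reference method's
#' residual masks, runs the agreement and Deauville-regression batteries,
#' draws the comparison plots, and writes a manifest with an MD5 checksum
#' for every artifact. Re-running with the same config produces
#' byte-identical files.
#'
#' @param config a [run_config()].
#' @return list with `records` (metrics data.frame), `agreement`,
#'   `ds_regression`, and `manifest` (data.frame of file, md5).
#' @export
run_full_study <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(config), file.path(out, "run_config.json"),
                       auto_unbox = TRUE, digits = NA)

  template <- default_phantom_template(psf_fwhm = config$psf_fwhm,
                                       noise_sigma = config$noise_sigma,
                                       rng_seed = config$seed)
  cohort <- default_cohort_spec(n_patients = config$n_patients,
                                rng_seed = config$seed)
  scans <- generate_cohort(cohort, template)
  write_cohort(scans, file.path(out, "volumes"),
               write_masks = FALSE, compress = FALSE)

  refs <- default_reference_vois()
  if (config$write_masks)
    dir.create(file.path(out, "masks"), showWarnings = FALSE)

  all_records <- list()
  ds_by_scan <- list()
  for (s in scans) {
    liver_mean <- reference_mean(s$volume, refs$liver)
    med_mean <- reference_mean(s$volume, refs$mediastinum)
    queries <- queries_for_scan(s$volume, s$baseline_lesions,
                                margin_mm = config$search_margin_mm)
    res <- segment_scan(s$volume, queries, liver_mean, med_mean,
                        s$patient_id, s$timepoint,
                        methods = config$methods,
                        gate = s$timepoint != "PET1",
                        gate_ratio = config$gate_ratio,
                        vliver_rule = config$vliver_rule)
    if (s$timepoint != "PET1") {
      ref_segs <- res$segmentations[[config$ds_reference_method]]
      residual <- vapply(ref_segs, function(sg)
        if (any(sg$mask)) max(s$volume$values[sg$mask]) else NA_real_,
        numeric(1))
      residual <- residual[is.finite(residual)]
      ds <- assign_deauville(
        if (length(residual)) max(residual) else NA_real_,
        med_mean, liver_mean, ds5_factor = config$ds5_factor)$ds
      res$records$ds <- ds
      ds_by_scan[[paste(s$patient_id, s$timepoint)]] <- ds
    }
    if (config$write_masks) {
      for (method in names(res$segmentations))
        for (lab in names(res$segmentations[[method]]))
          save_suv_volume(
            res$segmentations[[method]][[lab]]$mask,
            file.path(out, "masks", paste0(s$patient_id, "_", s$timepoint,
                                           "_", lab, "_", method, ".nii")),
            spacing = s$volume$spacing)
    }
    all_records[[length(all_records) + 1L]] <- res$records
  }
  records <- do.call(rbind, all_records)
  rownames(records) <- NULL
  utils::write.csv(records, file.path(out, "metrics.csv"), row.names = FALSE)

  agreement <- run_agreement_battery(records,
                                     loa_multiplier = config$loa_multiplier)
  utils::write.csv(agreement, file.path(out, "agreement.csv"),
                   row.names = FALSE)
  ds_reg <- run_ds_regression(records, outcome = config$ds_outcome)
  utils::write.csv(ds_reg, file.path(out, "ds_regression.csv"),
                   row.names = FALSE)

  if (config$write_plots) {
    dir.create(file.path(out, "plots"), showWarnings = FALSE)
    for (param in agreement_parameters)
      plot_agreement_panels(records, param, "PET1",
                            file.path(out, "plots",
                                      paste0("agreement_", param, "_PET1.png")),
                            loa_multiplier = config$loa_multiplier)
  }

  files <- sort(list.files(out, recursive = TRUE, full.names = FALSE))
  files <- setdiff(files, "run_manifest.csv")
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(out, files))),
    stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(out, "run_manifest.csv"),
                   row.names = FALSE)
  list(records = records, agreement = agreement, ds_regression = ds_reg,
       manifest = manifest)
}
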