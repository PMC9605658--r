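# Small phantom builders shared across the test files. All geometry is in mm
# on an `extent`-sized field; the lesion, liver and mediastinum regions are
# placed at fixed fractions of the extent so they stay disjoint for lesion
# radii up to ~25 mm at the default 96 x 96 x 72 mm extent (up to ~12 mm at
# the small 64 mm extent).

lesion_center_for <- function(extent) extent * c(0.60, 0.70, 0.50)

make_lesion_phantom <- function(radius = 10, uptake = 8, spacing = 2,
                                background = 0.5, liver_suv = 2,
                                med_suv = 1.2, het = 0, psf = 0, noise = 0,
                                seed = 1, extent = c(96, 96, 72)) {
  grid <- round(extent / spacing)
  lesion_ctr <- lesion_center_for(extent)
  liver_r <- min(10, 0.12 * min(extent))
  med_r <- min(7, 0.09 * min(extent))
  spec <- phantom_spec(
    grid_shape = grid, voxel_spacing = spacing, background_suv = background,
    liver_region = voi_sphere(extent * c(0.20, 0.20, 0.50), liver_r,
                              label = "liver"),
    liver_suv = liver_suv,
    mediastinum_region = voi_sphere(extent * c(0.80, 0.20, 0.50), med_r,
                                    label = "mediastinum"),
    mediastinum_suv = med_suv,
    lesions = list(lesion_spec(lesion_ctr, radius = radius, uptake = uptake,
                               heterogeneity_amp = het, label = "L1")),
    psf_fwhm = psf, noise_sigma = noise, rng_seed = seed)
  ph <- generate_phantom(spec)
  ph$spec <- spec
  ph$lesion_center <- lesion_ctr
  ph$query <- query_from_voi(ph$volume,
                             voi_sphere(lesion_ctr, radius + 8, label = "L1"),
                             label = "L1")
  ph
}

# Records table for a synthetic cohort where all methods agree perfectly:
# handy degenerate input for the agreement battery.
identical_method_records <- function(n_patients = 8, seed = 99) {
  set.seed(seed)
  rows <- list()
  for (p in seq_len(n_patients)) {
    base <- c(suvmean = runif(1, 3, 8), mtv_ml = runif(1, 50, 400))
    for (tp in c("PET1", "PET2", "PET3")) {
      fac <- switch(tp, PET1 = 1, PET2 = runif(1, 0.2, 0.6), PET3 = 0)
      for (m in SEGMENTATION_METHODS) {
        mtv <- base["mtv_ml"] * fac
        sm <- if (fac > 0) base["suvmean"] else 0
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = sprintf("P%02d", p), timepoint = tp, method = m,
          suvmean = unname(sm), mtv_ml = unname(mtv),
          tlg = unname(mtv * sm), ds = NA_integer_,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
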