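test_that("noiseless uniform sphere reproduces analytic volume and uptake", {
  ph <- make_lesion_phantom(radius = 10, spacing = 2, uptake = 8,
                            background = 0.5)
  gt <- ph$ground_truth[[1]]
  # voxelized truth volume within one voxel volume of 4/3*pi*10^3 mm^3
  expect_lt(abs(gt$voxel_volume_ml - 4 / 3 * pi * 1000 / 1000), 0.15)
  expect_equal(gt$analytic_volume_ml, 4 / 3 * pi * 1000 / 1000)
  # no corruption applied: lesion voxels are exactly the uptake
  expect_equal(max(ph$volume$values), 8)
  expect_equal(unique(ph$volume$values[gt$mask]), 8)
  expect_gte(min(ph$volume$values), 0)
})

test_that("voxelized truth volume converges to the analytic volume", {
  analytic <- 4 / 3 * pi * 10^3 / 1000
  errs <- vapply(c(4, 2, 1), function(sp) {
    ph <- make_lesion_phantom(radius = 10, spacing = sp)
    abs(ph$ground_truth[[1]]$voxel_volume_ml - analytic)
  }, numeric(1))
  expect_true(all(diff(errs) <= 0))
  expect_lt(errs[3], 0.05 * analytic)
})

test_that("PSF blur lowers the peak toward the closed-form centre value", {
  ph <- make_lesion_phantom(radius = 10, spacing = 2, uptake = 8,
                            background = 0.5, psf = 6)
  suvmax <- max(ph$volume$values)
  expect_lt(suvmax, 8)
  expect_gt(suvmax, 0.5)
  sigma <- 6 / (2 * sqrt(2 * log(2)))
  expected <- blurred_sphere_center(8, 0.5, 10, sigma)
  expect_lt(abs(suvmax - expected) / expected, 0.05)
})

test_that("noise is zero-mean over the background and clipped at zero", {
  ph <- make_lesion_phantom(radius = 8, spacing = 2, background = 1,
                            noise = 0.1, seed = 7)
  # background voxels: outside every painted region, away from nothing else
  shell <- suv_volume(array(1, ph$spec$grid_shape), ph$spec$voxel_spacing)
  bg <- !(voi_to_mask(shell, ph$spec$liver_region) |
          voi_to_mask(shell, ph$spec$mediastinum_region) |
          ph$ground_truth[[1]]$mask)
  resid <- ph$volume$values[bg] - 1
  expect_lt(abs(mean(resid)), 3 * 0.1 / sqrt(sum(bg)))
  expect_gte(min(ph$volume$values), 0)
})

test_that("phantom generation is deterministic under a fixed seed", {
  a <- make_lesion_phantom(noise = 0.2, seed = 11)
  b <- make_lesion_phantom(noise = 0.2, seed = 11)
  expect_identical(a$volume$values, b$volume$values)
  c <- make_lesion_phantom(noise = 0.2, seed = 12)
  expect_false(identical(a$volume$values, c$volume$values))
})

test_that("invalid phantom specs fail naming the offending region", {
  base <- function(lesions, ...) phantom_spec(
    grid_shape = c(24, 24, 24), voxel_spacing = 2, background_suv = 0.5,
    liver_region = voi_sphere(c(10, 10, 24), 6), liver_suv = 2,
    mediastinum_region = voi_sphere(c(38, 10, 24), 5), mediastinum_suv = 1.2,
    lesions = lesions, ...)
  expect_error(base(list(lesion_spec(c(44, 40, 24), 8, 8))),
               "outside the grid")
  expect_error(base(list(lesion_spec(c(12, 12, 24), 8, 8))), "liver")
  expect_error(phantom_spec(
    grid_shape = c(24, 24, 24), voxel_spacing = 2, background_suv = 1.5,
    liver_region = voi_sphere(c(10, 10, 24), 6), liver_suv = 2,
    mediastinum_region = voi_sphere(c(38, 10, 24), 5), mediastinum_suv = 1.2),
    "ordering")
  expect_error(lesion_spec(c(0, 0, 0), 5, uptake = 4, heterogeneity_amp = 4),
               "heterogeneity_amp")
})

test_that("cohort has the right shape, response monotonicity and determinism", {
  tmpl <- default_phantom_template(psf_fwhm = 0, noise_sigma = 0)
  cs <- cohort_spec(n_patients = 3, rng_seed = 5)
  scans <- generate_cohort(cs, tmpl)
  expect_length(scans, 9L)
  expect_identical(vapply(scans, `[[`, character(1), "timepoint"),
                   rep(c("PET1", "PET2", "PET3"), 3))
  for (p in unique(vapply(scans, `[[`, character(1), "patient_id"))) {
    ps <- Filter(function(s) s$patient_id == p, scans)
    up <- vapply(ps, function(s) {
      if (length(s$ground_truth) == 0) 0
      else max(vapply(s$ground_truth, `[[`, numeric(1), "true_peak_uptake"))
    }, numeric(1))
    expect_true(all(diff(up) <= 1e-12)) # PET1 >= PET2 >= PET3
  }
  scans2 <- generate_cohort(cs, tmpl)
  expect_identical(scans[[4]]$volume$values, scans2[[4]]$volume$values)
})

test_that("forced clearance empties all PET3 truth and scores DS 1", {
  tmpl <- default_phantom_template(psf_fwhm = 0, noise_sigma = 0)
  cs <- cohort_spec(n_patients = 3, rng_seed = 2,
                    response_model = list(
                      pet2 = list(uptake_shrink = c(0.4, 0.6),
                                  radius_shrink = c(0.5, 0.7),
                                  clear_prob = 0),
                      pet3 = list(uptake_shrink = c(0.1, 0.2),
                                  radius_shrink = c(0.2, 0.4),
                                  clear_prob = 1)))
  scans <- generate_cohort(cs, tmpl)
  pet3 <- Filter(function(s) s$timepoint == "PET3", scans)
  expect_true(all(vapply(pet3, function(s) length(s$ground_truth) == 0,
                         logical(1))))
  expect_true(all(vapply(pet3, `[[`, integer(1), "true_ds") == 1L))
})
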