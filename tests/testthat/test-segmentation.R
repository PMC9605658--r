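test_that("computed thresholds follow each method's formula exactly", {
  ph <- make_lesion_phantom(radius = 10, spacing = 2, uptake = 10,
                            background = 0.5)
  q <- ph$query
  liver <- 2.0
  expect_equal(segment_v41(ph$volume, q)$applied_threshold, 0.41 * 10)
  expect_equal(segment_v25(ph$volume, q)$applied_threshold, 2.5)
  expect_equal(segment_vliver(ph$volume, q, liver)$applied_threshold,
               1.5 * liver)
  am <- segment_am(ph$volume, q, liver)
  # uniform lesion: the 70% isocontour is the whole lesion, I(mean) = uptake
  expect_equal(am$isocontour_mean, 10)
  expect_equal(am$applied_threshold, 0.15 * 10 + liver)
})

test_that("all four methods recover a uniform lesion exactly", {
  ph <- make_lesion_phantom(radius = 10, spacing = 2, uptake = 8,
                            background = 0.5)
  truth <- ph$ground_truth[[1]]$mask
  for (m in SEGMENTATION_METHODS) {
    seg <- segment_lesion(ph$volume, ph$query, m, liver_mean = 2)
    expect_identical(seg$mask, truth)
  }
})

test_that("threshold ordering implies mask nesting", {
  ph <- make_lesion_phantom(radius = 10, spacing = 2, uptake = 10,
                            background = 0.5, het = 6, psf = 5,
                            noise = 0.1, seed = 4)
  segs <- lapply(SEGMENTATION_METHODS, function(m)
    segment_lesion(ph$volume, ph$query, m, liver_mean = 2))
  for (i in seq_along(segs)) for (j in seq_along(segs)) {
    if (segs[[i]]$applied_threshold <= segs[[j]]$applied_threshold)
      expect_true(all(segs[[j]]$mask <= segs[[i]]$mask),
                  info = paste(segs[[i]]$method, "vs", segs[[j]]$method))
  }
  # direct corollary: 4.1 > 2.5 so the V2.5 mask contains the V41% mask
  v41 <- segs[[match("v41", SEGMENTATION_METHODS)]]
  v25 <- segs[[match("v25", SEGMENTATION_METHODS)]]
  expect_true(all(v41$mask <= v25$mask))
})

test_that("graded lesion: V41% excludes the rim and AM matches a two-pass oracle", {
  ph <- make_lesion_phantom(radius = 10, spacing = 2, uptake = 10,
                            background = 0.5, het = 7) # rim SUV 3
  q <- ph$query
  truth_vol <- ph$ground_truth[[1]]$voxel_volume_ml
  search <- voi_to_mask(ph$volume, q$search_voi)
  # the lesion centre need not sit on a voxel centre, so the observed
  # SUVmax is slightly below the nominal peak uptake
  imax <- max(ph$volume$values[search])
  v41 <- segment_v41(ph$volume, q)
  m41 <- extract_metrics(ph$volume, v41)
  expect_lt(m41$mtv_ml, truth_vol) # rim voxels below 41% of Imax excluded
  # brute-force check of the excluded set
  expect_identical(v41$mask,
                   naive_segment(ph$volume, search, q$seed, 0.41 * imax))

  # AM two-pass oracle: isocontour >= 70% of Imax, mean over it, threshold
  iso <- naive_segment(ph$volume, search, q$seed, 0.7 * imax)
  imean <- mean(ph$volume$values[iso])
  am <- segment_am(ph$volume, q, liver_mean = 2)
  expect_equal(am$isocontour_mean, imean)
  expect_equal(am$applied_threshold, 0.15 * imean + 2)
  expect_identical(am$mask,
                   naive_segment(ph$volume, search, q$seed,
                                 0.15 * imean + 2))
  expect_gte(am$applied_threshold, 2) # AM threshold never below liver mean
})

test_that("Vliver eligibility rule gates faint lesions", {
  ph <- make_lesion_phantom(radius = 10, spacing = 2, uptake = 2.8,
                            background = 0.5)
  seg <- segment_vliver(ph$volume, ph$query, liver_mean = 2.0)
  expect_false(seg$eligible)
  expect_false(any(seg$mask))
  expect_match(seg$note, "below liver criterion")
  # ratio 1.4 is <= 1.5; raising the lesion above the criterion segments it
  ph2 <- make_lesion_phantom(radius = 10, spacing = 2, uptake = 8,
                             background = 0.5)
  seg2 <- segment_vliver(ph2$volume, ph2$query, liver_mean = 2.0)
  expect_true(seg2$eligible)
  expect_identical(seg2$mask, ph2$ground_truth[[1]]$mask)
  # alternate reading: eligibility only, voxels cut at the liver mean itself
  seg3 <- segment_vliver(ph2$volume, ph2$query, liver_mean = 2.0,
                         rule = "eligibility_only")
  expect_equal(seg3$applied_threshold, 2.0)
  expect_true(all(seg2$mask <= seg3$mask))
})

test_that("lesions below an absolute threshold give empty masks, not errors", {
  ph <- make_lesion_phantom(radius = 10, spacing = 2, uptake = 2.0,
                            background = 0.5)
  expect_warning(seg <- segment_v25(ph$volume, ph$query), "below threshold")
  expect_false(any(seg$mask))
  expect_match(seg$note, "below threshold")
  m <- extract_metrics(ph$volume, seg)
  expect_equal(m$mtv_ml, 0)
  expect_equal(m$tlg, 0)
})

test_that("connected component from seed matches its definition", {
  bin <- array(FALSE, c(8, 8, 8))
  bin[2:3, 2:3, 2:3] <- TRUE   # blob A
  bin[6:7, 6:7, 6:7] <- TRUE   # blob B
  cc <- connected_component_from_seed(bin, c(2, 2, 2))
  expect_equal(sum(cc), 8L)
  expect_true(all(which(cc) %in% which(bin)))
  expect_false(any(cc[6:7, 6:7, 6:7]))

  single <- array(FALSE, c(4, 4, 4)); single[2, 2, 2] <- TRUE
  expect_equal(sum(connected_component_from_seed(single, c(2, 2, 2))), 1L)

  # diagonal touching: connected under 26-connectivity, not under 6
  diag2 <- array(FALSE, c(4, 4, 4))
  diag2[1, 1, 1] <- TRUE; diag2[2, 2, 2] <- TRUE
  expect_equal(sum(connected_component_from_seed(diag2, c(1, 1, 1))), 2L)
  expect_equal(sum(connected_component_from_seed(diag2, c(1, 1, 1),
                                                 connectivity = 6)), 1L)
  # unset seed: empty result
  expect_equal(sum(connected_component_from_seed(diag2, c(3, 3, 3))), 0L)
})

test_that("flood fill agrees with the naive stack oracle on random grids", {
  set.seed(8)
  for (rep in 1:5) {
    bin <- array(runif(14^3) < 0.35, c(14, 14, 14))
    seed <- c(7, 7, 7)
    bin[7, 7, 7] <- TRUE
    expect_identical(connected_component_from_seed(bin, seed),
                     naive_cc(bin, seed))
    expect_identical(connected_component_from_seed(bin, seed, 6),
                     naive_cc(bin, seed, connectivity = 6))
  }
})

test_that("segmentation is deterministic and the isocontour stays in the VOI", {
  ph <- make_lesion_phantom(radius = 9, spacing = 2, uptake = 9, het = 4,
                            psf = 4, noise = 0.15, seed = 6)
  a <- segment_am(ph$volume, ph$query, liver_mean = 2)
  b <- segment_am(ph$volume, ph$query, liver_mean = 2)
  expect_identical(a$mask, b$mask)
  search <- voi_to_mask(ph$volume, ph$query$search_voi)
  expect_true(all(a$mask <= search))
  # every masked voxel is at or above the applied threshold
  expect_true(all(ph$volume$values[a$mask] >= a$applied_threshold))
})
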