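# Threshold, boundary crop, island and dead-space removal, region partition.

test_that("threshold_air uses a strict inequality and validates input", {
  v <- volume_image(array(40, c(4, 4, 4)), c(1, 1, 1))
  expect_equal(sum(threshold_air(v)$data), 0)

  v$data[2, 2, 2] <- -400  # exactly at the level: tissue
  expect_equal(sum(threshold_air(v)$data), 0)
  v$data[2, 2, 2] <- -400.001
  expect_equal(sum(threshold_air(v)$data), 1)

  v$data[1, 1, 1] <- NaN
  expect_aw_error(threshold_air(v), "aw_data_error")

  # two-valued phantom: the mask is exactly the rendered air set
  ph <- make_phantom(default_phantom_spec(voxel_spacing = rep(1, 3), noise_sd = 0), 1)
  expect_identical(threshold_air(ph$volume)$data, ph$volume$data < -400)
})

test_that("threshold monotonicity: stricter level gives a subset", {
  ph <- make_phantom(default_phantom_spec(voxel_spacing = rep(1, 3), noise_sd = 50), 1)
  m400 <- threshold_air(ph$volume, -400)$data
  m300 <- threshold_air(ph$volume, -300)$data
  expect_true(all(m300[m400]))
})

test_that("crop_boundaries keeps the analytic slab and validates planes", {
  spec <- tube_spec(r = 8, L = 60, spacing = 0.5)
  ph <- make_phantom(spec, 1)
  m <- threshold_air(ph$volume)
  cr <- crop_boundaries(m, landmark(ph$landmarks, "PNS"), landmark(ph$landmarks, "BEP"))
  expect_equal(cr$z_top, 60)
  expect_equal(cr$z_bottom, 0)
  expect_equal(sum(cr$data) * prod(cr$spacing), pi * 64 * 60, tolerance = 0.02)
  expect_true(all(which(apply(cr$data, 3, any)) %in% airwaymorph:::slab_slices(cr)))

  expect_aw_error(crop_boundaries(m, c(0, 0, 10), c(0, 0, 50)), "aw_boundary_error")
  expect_aw_error(crop_boundaries(m, c(0, 0, 500), c(0, 0, 400)), "aw_boundary_error")

  # anterior cut: everything in front of the PNS y is gone
  expect_aw_error(
    {
      cut <- crop_boundaries(m, c(0, -20, 60), c(0, -20, 0))  # PNS behind the lumen
      remove_islands(cut)
    }, "aw_empty_input")
})

test_that("remove_islands keeps exactly the spanning components", {
  spec <- tube_spec(r = 6, L = 40, spacing = 1)
  ph <- make_phantom(spec, 1)
  seg0 <- crop_boundaries(threshold_air(ph$volume),
                          landmark(ph$landmarks, "PNS"),
                          landmark(ph$landmarks, "BEP"))
  # single spanning component: identity
  expect_identical(remove_islands(seg0)$data, seg0$data)

  # detached 5-voxel blob: removed, count decreases by exactly 5
  blob <- seg0
  blob$data[3:7, 2, 20] <- TRUE
  expect_equal(sum(blob$data), sum(seg0$data) + 5)
  expect_equal(sum(remove_islands(blob)$data), sum(seg0$data))

  # two disjoint spanning channels are both kept
  two <- seg0
  d <- dim(two$data)
  two$data[] <- FALSE
  two$data[3, 3, ] <- TRUE
  two$data[d[1] - 2, d[2] - 2, ] <- TRUE
  sl <- airwaymorph:::slab_slices(two)
  two$data[, , setdiff(seq_len(d[3]), sl)] <- FALSE
  expect_equal(sum(remove_islands(two)$data), sum(two$data))

  # nothing spans: fall back to the largest component, with a warning
  ns <- seg0
  ns$data[] <- FALSE
  ns$data[4:6, 4:6, 10:12] <- TRUE
  ns$data[10, 10, 20] <- TRUE
  expect_warning(out <- remove_islands(ns), "largest")
  expect_equal(sum(out$data), 27)

  empty <- seg0; empty$data[] <- FALSE
  expect_aw_error(remove_islands(empty), "aw_empty_input")
})

test_that("slice descent removes upward-opening pockets but not the lumen", {
  # straight tube: identity
  spec <- tube_spec(r = 6, L = 40, spacing = 1)
  ph <- make_phantom(spec, 1)
  m <- remove_islands(crop_boundaries(threshold_air(ph$volume),
                                      landmark(ph$landmarks, "PNS"),
                                      landmark(ph$landmarks, "BEP")))
  expect_identical(remove_dead_space(m)$data, m$data)

  # phantom with pockets: above the attachment channel, cleaned per-slice
  # areas equal the lumen-only analytic areas
  spec2 <- default_phantom_spec(noise_sd = 0, with_islands = FALSE)
  ph2 <- make_phantom(spec2, 1)
  m2 <- remove_dead_space(remove_islands(crop_boundaries(
    threshold_air(ph2$volume),
    landmark(ph2$landmarks, "PNS"), landmark(ph2$landmarks, "BEP"))))
  prof <- cross_section_profile(m2)
  # mouth pocket spans z in [22.4, 34.4], attachment channel below 24.0
  zcheck <- prof$z[prof$z > 25 & prof$z < 34]
  lumen_area <- spec2$area_profile(spec2$axis_length - zcheck)
  meas <- prof$area[match(zcheck, prof$z)]
  expect_true(all(abs(meas / lumen_area - 1) < 0.03))

  # vallecular pocket (area ~50 mm^2 each slice) does not displace the MCA
  tr <- analytic_truth(spec2)
  mca <- find_mca(prof)
  expect_equal(mca$MCA, tr$MCA[tr$region == "total"], tolerance = 0.03)

  # seed errors
  expect_aw_error(remove_dead_space(m, seed_point = c(100, 100, 0)), "aw_seed_error")
})

test_that("cleanup never adds voxels (monotonicity), across random phantoms", {
  for (s in 1:3) {
    spec <- default_phantom_spec(voxel_spacing = rep(1, 3), noise_sd = 30)
    spec <- perturb_phantom(spec, seed = s)
    ph <- make_phantom(spec, seed = s)
    m <- crop_boundaries(threshold_air(ph$volume),
                         landmark(ph$landmarks, "PNS"),
                         landmark(ph$landmarks, "BEP"))
    mi <- remove_islands(m)
    md <- remove_dead_space(mi)
    expect_true(all(m$data[mi$data]))
    expect_true(all(mi$data[md$data]))
  }
})

test_that("partition is an exact disjoint cover with half-open slabs", {
  set.seed(4)
  for (s in 1:3) {
    spec <- perturb_phantom(default_phantom_spec(voxel_spacing = rep(1, 3),
                                                 noise_sd = 20), seed = s)
    ph <- make_phantom(spec, seed = s)
    seg <- segment_airway(ph$volume, ph$landmarks)
    counts <- vapply(seg$partition, function(m) sum(m$data), numeric(1))
    expect_equal(sum(counts), sum(seg$mask$data))
    overlap <- Reduce(`+`, lapply(seg$partition, function(m) m$data * 1L))
    expect_true(all(overlap <= 1L))
  }
})

test_that("equally spaced landmarks cut a constant tube into equal quarters", {
  spec <- tube_spec(r = 6, L = 40, spacing = 0.5,
                    fracs = c(TUV = 0.25, TEP = 0.75, BEP = 1.0))
  ph <- make_phantom(spec, 1)
  seg <- segment_airway(ph$volume, ph$landmarks)
  counts <- vapply(seg$partition, function(m) sum(m$data), numeric(1))
  slab <- pi * 36 * 10 / prod(spec$voxel_spacing)  # one quarter, in voxels
  expect_true(all(abs(counts - mean(counts)) <= pi * 36 / 0.25 + 1))
  expect_equal(as.numeric(counts / slab), rep(1, 4), tolerance = 0.03)
})

test_that("degenerate coincident landmarks give an empty region, not an error", {
  spec <- tube_spec(r = 6, L = 40, spacing = 1)
  ph <- make_phantom(spec, 1)
  lm <- ph$landmarks
  tuv <- landmark(lm, "TUV")
  lm2 <- landmark_set(rbind(lm, MUE = tuv))  # z(MUE) = z(TUV)
  m <- segment_airway(ph$volume, ph$landmarks)$mask
  part <- partition_regions(m, lm2)
  expect_equal(sum(part$oropharynx$data), 0)

  bad <- lm
  bad["TUV", 3] <- -5  # below BEP: ordering violated
  expect_aw_error(partition_regions(m, bad), "aw_ordering_error")
})

test_that("noise-free segmentation recovers the analytic lumen (Dice >= 0.98)", {
  spec <- default_phantom_spec(noise_sd = 0)  # 0.5 mm, pockets + islands
  ph <- make_phantom(spec, 1)
  seg <- segment_airway(ph$volume, ph$landmarks)
  ref <- lumen_voxels(spec, ph$volume)
  # restrict the reference to the cropped slab
  zs <- airwaymorph:::slice_heights(seg$mask)
  ref[, , zs > 66 | zs < 0] <- FALSE
  expect_gte(dice(seg$mask$data, ref), 0.98)
})
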