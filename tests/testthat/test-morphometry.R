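# Morphometric measurements against closed forms, a brute-force voxel
# oracle, and the phantom's analytic truth.

test_that("volume is voxel count times voxel volume", {
  arr <- array(FALSE, c(20, 10, 10))
  arr[seq_len(1000)] <- TRUE
  m <- airway_mask(arr, c(0.5, 0.5, 0.5))
  expect_equal(measure_volume(m), 125)
  empty <- airway_mask(array(FALSE, c(2, 2, 2)), c(1, 1, 1))
  expect_aw_error(measure_volume(empty), "aw_empty_input")
})

test_that("length is the boundary plane distance", {
  m <- airway_mask(array(TRUE, c(2, 2, 5)), c(1, 1, 1), z_top = 66.3, z_bottom = 0)
  expect_equal(measure_length(m), 66.3)
})

test_that("cylinder suite: V, SA, SA' within tolerance of closed forms", {
  cyl <- cylinder_mask(r = 8, L = 60, h = 0.5)
  expect_equal(measure_volume(cyl), pi * 64 * 60, tolerance = 0.02)
  s <- measure_surface(cyl)
  expect_equal(s$SA, 2 * pi * 8 * 60, tolerance = 0.04)
  expect_equal(s$SA_closed, 2 * pi * 8 * 60 + 2 * pi * 64, tolerance = 0.04)
  expect_lt(s$SA, s$SA_closed)
})

test_that("voxel-face surface variant is exact on boxes", {
  one <- airway_mask(array(TRUE, c(1, 1, 1)), c(1, 1, 1))
  s <- measure_surface(one, method = "voxel_face")
  expect_equal(s$SA_closed, 6)
  expect_equal(s$SA, 4)
  box <- airway_mask(array(TRUE, c(4, 3, 5)), c(1, 1, 1))
  sb <- measure_surface(box, method = "voxel_face")
  expect_equal(sb$SA_closed, 2 * (4 * 3 + 4 * 5 + 3 * 5))
})

test_that("cross-section profile matches the stated area profile", {
  spec <- constricted_spec(a_min = 80, at = 0.6)
  ph <- make_phantom(spec, 1)
  seg <- segment_airway(ph$volume, ph$landmarks)
  prof <- cross_section_profile(seg$mask)
  expect_true(all(diff(prof$z) < 0))
  analytic <- spec$area_profile(spec$axis_length - prof$z)
  expect_true(all(abs(prof$area / analytic - 1) < 0.03))
  # constant tube: all slice areas within one-voxel discretization
  tube <- cylinder_mask(r = 8, L = 20, h = 0.5)
  pt <- cross_section_profile(tube)
  expect_lt(max(pt$area) - min(pt$area), 2)
  expect_equal(max(abs(pt$area - pi * 64)), 0, tolerance = 3)
})

test_that("find_mca picks the minimum with the superior tie rule", {
  prof <- data.frame(z = c(30, 20, 10, 5), area = c(201, 150, 80, 150),
                     slice = 4:1)
  expect_equal(find_mca(prof)$MCA, 80)
  expect_equal(find_mca(prof)$MCA_z, 10)

  tie <- data.frame(z = c(30, 20, 10), area = c(80, 100, 80), slice = 3:1)
  expect_equal(find_mca(tie)$MCA_z, 30)  # most superior of the equal minima

  allz <- data.frame(z = c(2, 1), area = c(0, 0), slice = 1:2)
  expect_aw_error(find_mca(allz), "aw_empty_input")

  # zero-area boundary slices are rounding, interior zeros are data errors
  edge <- data.frame(z = 5:1, area = c(0, 10, 8, 12, 0), slice = 5:1)
  expect_equal(find_mca(edge)$MCA, 8)
  hole <- data.frame(z = 5:1, area = c(10, 8, 0, 12, 9), slice = 5:1)
  expect_aw_error(find_mca(hole), "aw_data_error")
})

test_that("MCA slice extents match a rasterized ellipse", {
  h <- 0.25
  xs <- seq(-12, 12, by = h); ys <- seq(-6, 6, by = h)
  ell <- outer((xs / 10)^2, (ys / 4)^2, `+`) <= 1
  d <- mca_dimensions(ell, c(h, h), origin = c(xs[1], ys[1]), midsagittal_x = 0)
  expect_equal(d$LAT, 20, tolerance = h / 20 * 1.5)
  expect_equal(d$AP, 8, tolerance = h / 8 * 2.1)

  circ <- outer((xs / 5)^2, (ys / 5)^2, `+`) <= 1
  d2 <- mca_dimensions(circ, c(h, h), origin = c(xs[1], ys[1]))
  expect_equal(d2$LAT, 10, tolerance = 0.06)
  expect_equal(d2$LAT / d2$AP, 1, tolerance = 0.06)

  # crescent-like slice missing the midsagittal column: centroid fallback
  cres <- ell
  cres[abs(xs) < 2, ] <- FALSE
  expect_warning(d3 <- mca_dimensions(cres, c(h, h), origin = c(xs[1], ys[1])),
                 "centroid")
  expect_true(d3$AP > 0)
  expect_aw_error(mca_dimensions(ell & FALSE, c(h, h)), "aw_empty_input")
})

test_that("derived parameters follow their defining formulas", {
  dp <- derive_parameters(V = 100, L = 10, SA_closed = 50, MCA = 5,
                          LAT = 6, AP = 3)
  expect_equal(dp$meanCSA, 10)
  expect_equal(dp$lat_ap_ratio, 2)
  expect_equal(dp$uniformity, 0.5)

  # sphere: sphericity is exactly 1
  r <- 7.3
  dps <- derive_parameters(V = 4 / 3 * pi * r^3, L = 2 * r,
                           SA_closed = 4 * pi * r^2, MCA = pi * r^2,
                           LAT = 2 * r, AP = 2 * r)
  expect_equal(dps$sphericity, 1, tolerance = 1e-12)

  # cylinder with height = diameter: closed form pi^(1/3) (12 pi)^(2/3) / (6 pi)
  r <- 5
  dpc <- derive_parameters(V = 2 * pi * r^3, L = 2 * r, SA_closed = 6 * pi * r^2,
                           MCA = pi * r^2, LAT = 2 * r, AP = 2 * r)
  expect_equal(dpc$sphericity, pi^(1 / 3) * (12 * pi)^(2 / 3) / (6 * pi),
               tolerance = 1e-12)

  expect_aw_error(derive_parameters(1, 0, 1, 1, 1, 1), "aw_undefined_parameter")
  expect_aw_error(derive_parameters(1, 1, 1, 1, 1, 0), "aw_undefined_parameter")
  expect_aw_error(derive_parameters(1, 1, 0, 1, 1, 1), "aw_undefined_parameter")
})

test_that("sphericity of voxelized spheres converges monotonically to 1", {
  err <- vapply(c(1.0, 0.5, 0.25), function(h) {
    m <- ball_mask(r = 8, h = h)
    s <- measure_surface(m)
    abs(1 - pi^(1 / 3) * (6 * measure_volume(m))^(2 / 3) / s$SA_closed)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], 0.01)
})

test_that("brute-force voxel oracle agrees exactly on small random masks", {
  set.seed(31)
  for (rep in 1:5) {
    # a blobby but z-contiguous mask: union of stacked random balls
    d <- c(24, 20, 28)
    arr <- array(FALSE, d)
    cx <- runif(1, 8, 16); cy <- runif(1, 7, 13)
    for (k in seq_len(d[3])) {
      r <- runif(1, 2.5, 6)
      cx <- min(max(cx + rnorm(1, 0, 0.8), 7), 17)
      cy <- min(max(cy + rnorm(1, 0, 0.6), 6), 14)
      arr[, , k] <- outer((seq_len(d[1]) - cx)^2, (seq_len(d[2]) - cy)^2, `+`) <= r^2
    }
    sp <- c(0.7, 0.9, 1.1)
    m <- airway_mask(arr, sp, origin = c(0, 0, 0))

    # oracle: naive per-voxel enumeration in plain R loops
    v_oracle <- 0
    areas <- numeric(d[3])
    for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1]))
      if (arr[i, j, k]) {
        v_oracle <- v_oracle + prod(sp)
        areas[k] <- areas[k] + sp[1] * sp[2]
      }
    expect_equal(measure_volume(m), v_oracle)
    prof <- cross_section_profile(m)
    expect_equal(prof$area, rev(areas))

    mca <- find_mca(prof)
    expect_equal(mca$MCA, min(areas[areas > 0]))

    sl <- m$data[, , mca$slice]
    dims <- mca_dimensions(sl, sp[1:2], origin = c(0, 0),
                           midsagittal_x = (round(mean(row(sl)[sl])) - 1) * sp[1])
    lat_o <- 0
    for (j in seq_len(d[2])) {
      w <- which(sl[, j])
      if (length(w)) lat_o <- max(lat_o, (max(w) - min(w) + 1) * sp[1])
    }
    expect_equal(dims$LAT, lat_o)
  }
})

test_that("measure_airway: region structure, additivity and MCA location", {
  spec <- constricted_spec(a_min = 80, at = 0.68)  # in the tongue-base slab
  ph <- make_phantom(spec, 1)
  seg <- segment_airway(ph$volume, ph$landmarks)
  par <- measure_airway(seg$mask, seg$partition)
  expect_identical(par$region, airway_regions())

  tot <- par[par$region == "total", ]
  reg <- par[par$region != "total", ]
  expect_equal(tot$V, sum(reg$V))              # exact: disjoint voxel cover
  expect_equal(tot$L, sum(reg$L))
  expect_equal(tot$MCA, min(reg$MCA))
  # the open (lateral) surface is additive; SA' is not, since every internal
  # cutting plane contributes a cap to both adjacent regions
  expect_equal(tot$SA, sum(reg$SA), tolerance = 0.01)

  expect_equal(tot$MCA, reg$MCA[reg$region == "tongue_base"])
  lm <- ph$landmarks
  expect_true(tot$MCA_z >= landmark(lm, "TEP")[3] &&
              tot$MCA_z < compute_mue(landmark(lm, "TUV"), landmark(lm, "TEP"))[3])

  expect_true(all(par$uniformity > 0 & par$uniformity <= 1 + 1e-9))
  expect_true(all(par$sphericity > 0 & par$sphericity <= 1.01))
  expect_true(all(par$SA < par$SA_closed))
})

test_that("uniformity is 1 for a constant tube, per region", {
  spec <- tube_spec(r = 7, L = 48, spacing = 0.5,
                    fracs = c(TUV = 0.25, TEP = 0.75, BEP = 1.0))
  ph <- make_phantom(spec, 1)
  seg <- segment_airway(ph$volume, ph$landmarks)
  par <- measure_airway(seg$mask, seg$partition)
  # slab quantization: a cutting plane through slice centers adds up to one
  # voxel slab to a region's volume, so tolerance is dz / shortest region
  tol <- spec$voxel_spacing[3] / min(par$L[par$region != "total"]) + 0.005
  expect_equal(par$uniformity, rep(1, 5), tolerance = tol)
})

test_that("voxel-analytic convergence on a clean 0.5 mm phantom", {
  spec <- default_phantom_spec(noise_sd = 0, with_pockets = FALSE,
                               with_islands = FALSE)
  ph <- make_phantom(spec, 1)
  seg <- segment_airway(ph$volume, ph$landmarks)
  par <- measure_airway(seg$mask, seg$partition)
  tr <- ph$truth
  expect_equal(par$V, tr$V, tolerance = 0.02)
  expect_equal(par$L, tr$L, tolerance = 1e-9)
  expect_equal(par$MCA, tr$MCA, tolerance = 0.03)
  expect_equal(par$SA_closed, tr$SA_closed, tolerance = 0.04)
  expect_equal(par$SA, tr$SA, tolerance = 0.04)
})
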