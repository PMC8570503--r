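# Morphometric parameters of a cleaned airway mask: volume, plane-to-plane
# length, open and closed surface area, per-slice cross-section profile,
# minimum cross-sectional area and its lateral / anteroposterior extents,
# and the derived shape parameters (mean cross-sectional area, LAT/AP ratio,
# uniformity, sphericity).

#' Airway volume
#' @param mask a cleaned [airway_mask()].
#' @return volume in mm^3 (foreground voxel count times voxel volume).
#' @export
measure_volume <- function(mask) {
  n <- sum(mask$data)
  if (n == 0) abort_empty("mask is empty; volume undefined")
  n * prod(mask$spacing)
}

#' Airway length perpendicular to the Frankfort plane
#' @param mask an [airway_mask()] with boundaries set.
#' @return `z_top - z_bottom` in mm (plane distance, not voxel extent).
#' @export
measure_length <- function(mask) {
  mask$z_top - mask$z_bottom
}

#' Airway surface area, open and closed
#'
#' The closed surface SA' consists of the lateral (mucosal) wall plus the
#' planar caps on the boundary planes; the open surface SA omits the caps
#' ("without the top and bottom").
#'
#' With `method = "mesh"` the lateral wall is triangulated by marching
#' tetrahedra on a lightly smoothed copy of the mask (Gaussian,
#' `smooth_sigma` voxels). To avoid rim artifacts the boundary slices are
#' first replicated outward, the mesh is clipped to the boundary slab, and
#' flat pixel-counted caps are added. `method = "voxel_face"` counts exposed
#' voxel faces instead; it is exact for axis-aligned boxes but overestimates
#' oblique and curved walls (by up to ~50% on spheres) and serves as a
#' cross-check variant only.
#'
#' @param mask a cleaned [airway_mask()].
#' @param method `"mesh"` (default) or `"voxel_face"`.
#' @param smooth_sigma mesh pre-smoothing in voxel units (default 1).
#' @return list with `SA` and `SA_closed` in mm^2.
#' @export
measure_surface <- function(mask, method = c("mesh", "voxel_face"),
                            smooth_sigma = 1.0) {
  method <- match.arg(method)
  if (!any(mask$data)) abort_empty("mask is empty; surface undefined")
  nz <- dim(mask$data)[3]
  nonempty <- which(apply(mask$data, 3, any))
  k0 <- min(nonempty); k1 <- max(nonempty)
  core <- mask$data[, , k0:k1, drop = FALSE]
  pixel_area <- mask$spacing[1] * mask$spacing[2]
  caps <- (sum(core[, , 1]) + sum(core[, , dim(core)[3]])) * pixel_area

  if (method == "voxel_face") {
    SA_closed <- voxel_face_area(core, mask$spacing)
    return(list(SA = SA_closed - caps, SA_closed = SA_closed))
  }

  nrep <- as.integer(ceiling(4 * smooth_sigma)) + 2L
  pad <- as.integer(ceiling(4 * smooth_sigma)) + 1L
  nc <- dim(core)
  ext <- array(FALSE, c(nc[1] + 2L * pad, nc[2] + 2L * pad,
                        nc[3] + 2L * (nrep + pad)))
  xi <- pad + seq_len(nc[1]); yi <- pad + seq_len(nc[2])
  ext[xi, yi, pad + nrep + seq_len(nc[3])] <- core
  for (r in seq_len(nrep)) {
    ext[xi, yi, pad + nrep + 1L - r] <- core[, , 1]
    ext[xi, yi, pad + nrep + nc[3] + r] <- core[, , dim(core)[3]]
  }
  field <- .cpp_smooth3d(as.numeric(ext), dim(ext), smooth_sigma)
  tris <- .cpp_march_tets(field, dim(ext), 0.5, mask$spacing)
  if (nrow(tris) == 0) abort_empty("no isosurface found (mask too small)")
  # triangle centroid z, in the extended lattice frame (voxel 0 at 0)
  cz <- (tris[, 3] + tris[, 6] + tris[, 9]) / 3
  zlo <- (pad + nrep - 0.5) * mask$spacing[3]
  zhi <- (pad + nrep + nc[3] - 1 + 0.5) * mask$spacing[3]
  keep <- cz >= zlo & cz <= zhi
  SA_lat <- sum(triangle_areas(tris[keep, , drop = FALSE]))
  list(SA = SA_lat, SA_closed = SA_lat + caps)
}

triangle_areas <- function(tris) {
  if (nrow(tris) == 0) return(numeric(0))
  ux <- tris[, 4] - tris[, 1]; uy <- tris[, 5] - tris[, 2]; uz <- tris[, 6] - tris[, 3]
  vx <- tris[, 7] - tris[, 1]; vy <- tris[, 8] - tris[, 2]; vz <- tris[, 9] - tris[, 3]
  cx <- uy * vz - uz * vy; cy <- uz * vx - ux * vz; cz <- ux * vy - uy * vx
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

voxel_face_area <- function(core, spacing) {
  d <- dim(core)
  fx <- spacing[2] * spacing[3]; fy <- spacing[1] * spacing[3]
  fz <- spacing[1] * spacing[2]
  pad <- array(FALSE, d + 2L)
  pad[1 + seq_len(d[1]), 1 + seq_len(d[2]), 1 + seq_len(d[3])] <- core
  n_exposed <- function(shift_axis) {
    idx <- function(off) {
      i <- 1 + seq_len(d[1]) + off[1]; j <- 1 + seq_len(d[2]) + off[2]
      k <- 1 + seq_len(d[3]) + off[3]
      pad[i, j, k, drop = FALSE]
    }
    off <- c(0, 0, 0); off[shift_axis] <- 1L
    sum(core & !idx(off)) + sum(core & !idx(-off))
  }
  n_exposed(1) * fx + n_exposed(2) * fy + n_exposed(3) * fz
}

#' Per-slice cross-sectional area profile
#'
#' @param mask a cleaned [airway_mask()].
#' @return data frame of class `cross_section_profile` with columns `z` (mm,
#'   decreasing, superior to inferior), `area` (mm^2) and `slice` (lattice
#'   index), one row per lattice slice within the boundary slab.
#' @export
cross_section_profile <- function(mask) {
  sl <- slab_slices(mask)
  z <- slice_heights(mask)[sl]
  pixel_area <- mask$spacing[1] * mask$spacing[2]
  area <- apply(mask$data[, , sl, drop = FALSE], 3, sum) * pixel_area
  out <- data.frame(z = rev(z), area = rev(area), slice = rev(sl))
  class(out) <- c("cross_section_profile", "data.frame")
  out
}

#' Minimum cross-sectional area of a profile
#'
#' Zero-area slices at the slab boundaries (plane rounding) are ignored;
#' zero-area slices in the interior mean the airway is discontinuous after
#' cleanup and raise a data error rather than returning MCA = 0. Ties are
#' broken toward the most superior slice.
#'
#' @param profile a [cross_section_profile()].
#' @return list with `MCA` (mm^2), `MCA_z` (mm) and `slice` (lattice index).
#' @export
find_mca <- function(profile) {
  if (nrow(profile) == 0 || all(profile$area == 0))
    abort_empty("profile has no positive-area slice")
  pos <- which(profile$area > 0)
  core <- profile[min(pos):max(pos), , drop = FALSE]
  if (any(core$area == 0))
    abort_data("zero-area slice inside the airway at z=%.2f: mask is discontinuous",
               core$z[which(core$area == 0)[1]])
  i <- which.min(core$area)  # which.min returns the first = most superior
  list(MCA = core$area[i], MCA_z = core$z[i], slice = core$slice[i])
}

#' Lateral and anteroposterior extents of the MCA slice
#'
#' LAT is the maximum left-right foreground extent over all
#' anterior-posterior rows; AP is the foreground extent along the
#' anteroposterior axis on the midsagittal column (fallback: the column
#' through the slice centroid, with a warning). Extents are center-to-center
#' distances plus one voxel pitch, treating voxels as cells.
#'
#' @param slice_mask 2D logical matrix (x by y) of the MCA slice.
#' @param spacing in-plane spacing (dx, dy) in mm.
#' @param origin in-plane origin (x, y) of voxel (1, 1) center, mm.
#' @param midsagittal_x x position (mm) of the midsagittal plane, default 0.
#' @return list with `LAT` and `AP` in mm.
#' @export
mca_dimensions <- function(slice_mask, spacing, origin = c(0, 0),
                           midsagittal_x = 0) {
  if (!any(slice_mask)) abort_empty("MCA slice is empty")
  rows <- row(slice_mask)[slice_mask]
  cols <- col(slice_mask)[slice_mask]
  lat_by_row <- tapply(rows, cols, function(i) (max(i) - min(i) + 1L))
  LAT <- max(lat_by_row) * spacing[1]
  i_mid <- round((midsagittal_x - origin[1]) / spacing[1]) + 1
  if (i_mid < 1 || i_mid > nrow(slice_mask) || !any(slice_mask[i_mid, ])) {
    i_mid <- round(mean(rows))
    warning("midsagittal column is empty on the MCA slice; using the centroid column")
    if (!any(slice_mask[i_mid, ]))
      i_mid <- rows[which.min(abs(rows - mean(rows)))]
  }
  jj <- which(slice_mask[i_mid, ])
  AP <- (max(jj) - min(jj) + 1L) * spacing[2]
  list(LAT = LAT, AP = AP)
}

#' Derived airway shape parameters
#'
#' `meanCSA = V / L`, `lat_ap_ratio = LAT / AP`,
#' `uniformity = MCA / meanCSA`, and
#' `sphericity = pi^(1/3) * (6 V)^(2/3) / SA'` (1 for a sphere, < 1 for any
#' other shape; SA' is the closed surface area including caps).
#'
#' @param V volume mm^3.
#' @param L length mm.
#' @param SA_closed closed surface area mm^2.
#' @param MCA minimum cross-sectional area mm^2.
#' @param LAT,AP extents of the MCA slice, mm.
#' @return list with `meanCSA`, `lat_ap_ratio`, `uniformity`, `sphericity`.
#' @export
derive_parameters <- function(V, L, SA_closed, MCA, LAT, AP) {
  if (!isTRUE(L > 0)) abort_undefined_parameter("meanCSA undefined: length is zero")
  if (!isTRUE(AP > 0)) abort_undefined_parameter("lat_ap_ratio undefined: AP is zero")
  if (!isTRUE(SA_closed > 0)) abort_undefined_parameter("sphericity undefined: SA' is zero")
  meanCSA <- V / L
  list(meanCSA = meanCSA,
       lat_ap_ratio = LAT / AP,
       uniformity = MCA / meanCSA,
       sphericity = pi^(1 / 3) * (6 * V)^(2 / 3) / SA_closed)
}

#' Measure all airway parameters for the total airway and its regions
#'
#' @param mask the cleaned total-airway [airway_mask()].
#' @param partition a `region_partition` from [partition_regions()] (or
#'   `NULL` to measure the total airway only).
#' @param midsagittal_x x (mm) of the midsagittal plane (default 0).
#' @param surface_method passed to [measure_surface()].
#' @return data frame of class `airway_parameters`, one row per region, with
#'   columns region, V, L, SA, SA_closed, MCA, MCA_z, LAT, AP, meanCSA,
#'   lat_ap_ratio, uniformity, sphericity. Empty regions (degenerate
#'   landmark spacing) yield NA rows with a warning.
#' @export
measure_airway <- function(mask, partition = NULL, midsagittal_x = 0,
                           surface_method = "mesh") {
  masks <- c(list(total = mask), if (!is.null(partition)) unclass(partition))
  rows <- lapply(names(masks), function(region) {
    m <- masks[[region]]
    if (!any(m$data)) {
      warning(sprintf("region '%s' is empty; parameters set to NA", region))
      return(data.frame(region = region, V = NA_real_, L = measure_length(m),
                        SA = NA_real_, SA_closed = NA_real_, MCA = NA_real_,
                        MCA_z = NA_real_, LAT = NA_real_, AP = NA_real_,
                        meanCSA = NA_real_, lat_ap_ratio = NA_real_,
                        uniformity = NA_real_, sphericity = NA_real_))
    }
    V <- measure_volume(m)
    L <- measure_length(m)
    surf <- measure_surface(m, method = surface_method)
    prof <- cross_section_profile(m)
    mca <- find_mca(prof)
    slice2d <- m$data[, , mca$slice]
    dims <- mca_dimensions(slice2d, m$spacing[1:2], m$origin[1:2], midsagittal_x)
    dp <- derive_parameters(V, L, surf$SA_closed, mca$MCA, dims$LAT, dims$AP)
    data.frame(region = region, V = V, L = L, SA = surf$SA,
               SA_closed = surf$SA_closed, MCA = mca$MCA, MCA_z = mca$MCA_z,
               LAT = dims$LAT, AP = dims$AP, meanCSA = dp$meanCSA,
               lat_ap_ratio = dp$lat_ap_ratio, uniformity = dp$uniformity,
               sphericity = dp$sphericity)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("airway_parameters", "data.frame")
  out
}
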