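# Airway segmentation: HU thresholding, cropping to the anatomic boundary
# planes, removal of disconnected air ("islands") and of re-entrant pockets
# ("dead space"), and partition into the four landmark-bounded regions.
#
# Interpretation notes (these rules operationalize a manual workflow):
#  * Air is HU strictly below the threshold; a voxel exactly at -400 HU is
#    tissue.
#  * An island is a 3D component (26-connectivity) that does not span from
#    the superior to the inferior boundary slice; the breathing path does.
#  * Dead space is removed by seeded slice descent: starting from the seed
#    component on the top slice, each lower slice keeps only the 2D
#    components (8-connectivity) overlapping the voxels kept in the slice
#    above. Pockets reachable only by descending past their attachment and
#    re-ascending (mouth, valleculae) are thereby excluded.

#' Threshold a CT volume to an air mask
#'
#' @param volume a [volume_image()] in HU.
#' @param air_threshold HU level; foreground is `HU < air_threshold`
#'   (strict), default -400.
#' @return An [airway_mask()] spanning the full volume extent.
#' @export
threshold_air <- function(volume, air_threshold = -400) {
  if (any(!is.finite(volume$data)))
    abort_data("volume contains non-finite HU values")
  airway_mask(volume$data < air_threshold, volume$spacing, volume$origin)
}

#' Crop an airway mask to the PNS and BEP boundary planes
#'
#' Keeps voxels between the horizontal plane through the posterior nasal
#' spine (superior boundary) and the plane through the epiglottis base
#' (inferior boundary), and removes everything anterior to the PNS cut
#' (`y > y(PNS)`) through the whole slab. Comparisons use voxel centers;
#' voxels exactly on a boundary plane are kept.
#'
#' @param mask an [airway_mask()].
#' @param pns,bep landmark points (mm), `z(pns) > z(bep)`.
#' @return The cropped [airway_mask()] with `z_top = z(pns)`,
#'   `z_bottom = z(bep)`.
#' @export
crop_boundaries <- function(mask, pns, bep) {
  pns <- as.numeric(pns); bep <- as.numeric(bep)
  if (!(pns[3] > bep[3]))
    abort_boundary("superior plane z(PNS)=%.2f must lie above z(BEP)=%.2f",
                   pns[3], bep[3])
  z <- slice_heights(mask)
  half <- mask$spacing[3] / 2
  if (pns[3] > max(z) + half || bep[3] < min(z) - half)
    abort_boundary("boundary planes [%.2f, %.2f] fall outside the volume z extent [%.2f, %.2f]",
                   bep[3], pns[3], min(z), max(z))
  tol <- 1e-6  # mm; voxel centers within tol of a plane count as on it
  data <- mask$data
  zkill <- z > pns[3] + tol | z < bep[3] - tol
  if (any(zkill)) data[, , zkill] <- FALSE
  y <- axis_coords(mask, 2)
  ykill <- y > pns[2] + tol
  if (any(ykill)) data[, ykill, ] <- FALSE
  airway_mask(data, mask$spacing, mask$origin,
              z_top = pns[3], z_bottom = bep[3], region_tag = mask$region_tag)
}

#' Remove air islands from an airway mask
#'
#' Keeps only 3D connected components (26-connectivity) that intersect both
#' the top slice (at `z_top`) and the bottom slice (at `z_bottom`); loose air
#' parts are removed. If no component spans both boundaries, the largest
#' component is kept and a warning is emitted.
#'
#' @param mask an [airway_mask()] with boundaries set (see
#'   [crop_boundaries()]).
#' @return The cleaned [airway_mask()].
#' @export
remove_islands <- function(mask) {
  if (!any(mask$data)) abort_empty("mask is empty; nothing to clean")
  lab <- .cpp_label3d(as.logical(mask$data), dim(mask$data), 26L)
  dim(lab) <- dim(mask$data)
  sl <- slab_slices(mask)
  ktop <- max(sl); kbot <- min(sl)
  top_labels <- unique(lab[, , ktop]); top_labels <- top_labels[top_labels > 0]
  bot_labels <- unique(lab[, , kbot]); bot_labels <- bot_labels[bot_labels > 0]
  spanning <- intersect(top_labels, bot_labels)
  if (length(spanning) == 0) {
    warning("no air component spans the boundary planes; keeping the largest component")
    tab <- tabulate(lab[lab > 0])
    spanning <- which.max(tab)
  }
  data <- array(lab %in% spanning & mask$data, dim(mask$data))
  airway_mask(data, mask$spacing, mask$origin, mask$z_top, mask$z_bottom,
              mask$region_tag)
}

#' Remove dead space by seeded slice descent
#'
#' Retains, on the top slice, the 2D component (8-connectivity) containing
#' the seed, then walks down slice by slice keeping the 2D components that
#' overlap the kept set of the slice above. Anterior pockets connected to the
#' lumen only through an upward-opening attachment (mouth space, valleculae)
#' are excluded.
#'
#' @param mask an [airway_mask()] after island removal.
#' @param seed_point optional point (mm); must map to a foreground voxel on
#'   the top slice. Default: the most posterior foreground voxel of the top
#'   slice (ties broken toward the most posterior 2D component centroid).
#' @return The cleaned [airway_mask()].
#' @export
remove_dead_space <- function(mask, seed_point = NULL) {
  if (!any(mask$data)) abort_empty("mask is empty; nothing to clean")
  sl <- slab_slices(mask)
  ktop <- max(sl); kbot <- min(sl)
  top <- mask$data[, , ktop]
  if (!any(top)) abort_seed("top slice at z_top=%.2f has no foreground", mask$z_top)
  lab <- .cpp_label2d(top, 8L)
  if (is.null(seed_point)) {
    ymin <- min(col(top)[top])
    cand <- unique(lab[, ymin][top[, ymin]])
    if (length(cand) > 1) { # tie: most posterior centroid
      cy <- vapply(cand, function(l) mean(col(top)[lab == l]), numeric(1))
      cand <- cand[which.min(cy)]
    }
    seed_label <- cand[1]
  } else {
    seed_point <- as.numeric(seed_point)
    i <- round((seed_point[1] - mask$origin[1]) / mask$spacing[1]) + 1
    j <- round((seed_point[2] - mask$origin[2]) / mask$spacing[2]) + 1
    if (i < 1 || j < 1 || i > dim(top)[1] || j > dim(top)[2] || !top[i, j])
      abort_seed("seed point (%s) is not a foreground voxel on the top slice",
                 paste(signif(seed_point, 4), collapse = ", "))
    seed_label <- lab[i, j]
  }
  out <- array(FALSE, dim(mask$data))
  kept_prev <- lab == seed_label
  out[, , ktop] <- kept_prev
  if (ktop > kbot) for (k in seq(ktop - 1, kbot)) {
    cur <- mask$data[, , k]
    if (!any(cur)) { kept_prev <- cur; next }
    lab <- .cpp_label2d(cur, 8L)
    keep_labels <- unique(lab[kept_prev & cur])
    keep_labels <- keep_labels[keep_labels > 0]
    kept_prev <- array(lab %in% keep_labels, dim(cur)) & cur
    out[, , k] <- kept_prev
  }
  airway_mask(out, mask$spacing, mask$origin, mask$z_top, mask$z_bottom,
              mask$region_tag)
}

#' Partition an airway mask into the four anatomic regions
#'
#' Cutting planes are horizontal (parallel to the Frankfort plane) through
#' the landmarks. Voxels are assigned by center height z to: velopharynx
#' `z(TUV) <= z <= z(PNS)`, oropharynx `z(MUE) <= z < z(TUV)`, tongue base
#' `z(TEP) <= z < z(MUE)`, epiglottis `z(BEP) <= z < z(TEP)`. Half-open
#' intervals make the partition exact; MUE is derived from TUV and TEP when
#' not supplied.
#'
#' @param mask a cleaned total-airway [airway_mask()] cropped to
#'   `[z(BEP), z(PNS)]`.
#' @param landmarks a [landmark_set()] with PNS, TUV, TEP, BEP (MUE optional).
#' @return A named list of four region [airway_mask()]s, class
#'   `region_partition`.
#' @export
partition_regions <- function(mask, landmarks) {
  zl <- c(PNS = landmark(landmarks, "PNS")[3],
          TUV = landmark(landmarks, "TUV")[3],
          MUE = if ("MUE" %in% rownames(landmarks)) landmark(landmarks, "MUE")[3]
                else compute_mue(landmark(landmarks, "TUV"),
                                 landmark(landmarks, "TEP"))[3],
          TEP = landmark(landmarks, "TEP")[3],
          BEP = landmark(landmarks, "BEP")[3])
  if (any(diff(zl) > 1e-9))
    abort_ordering(
      "landmark heights must be ordered z(PNS) >= z(TUV) >= z(MUE) >= z(TEP) >= z(BEP), got %s",
      paste(sprintf("%s=%.2f", names(zl), zl), collapse = " "))
  z <- slice_heights(mask)
  tol <- 1e-6  # centers within tol of a cutting plane belong to the upper slab
  bands <- list(
    velopharynx = z >= zl[["TUV"]] - tol & z <= zl[["PNS"]] + tol,
    oropharynx  = z >= zl[["MUE"]] - tol & z < zl[["TUV"]] - tol,
    tongue_base = z >= zl[["TEP"]] - tol & z < zl[["MUE"]] - tol,
    epiglottis  = z >= zl[["BEP"]] - tol & z < zl[["TEP"]] - tol)
  tops <- c(velopharynx = zl[["PNS"]], oropharynx = zl[["TUV"]],
            tongue_base = zl[["MUE"]], epiglottis = zl[["TEP"]])
  bots <- c(velopharynx = zl[["TUV"]], oropharynx = zl[["MUE"]],
            tongue_base = zl[["TEP"]], epiglottis = zl[["BEP"]])
  out <- lapply(names(bands), function(region) {
    data <- mask$data
    data[, , !bands[[region]]] <- FALSE
    zt <- tops[[region]]; zb <- bots[[region]]
    if (!(zt > zb)) zt <- zb + 1e-9  # degenerate (coincident landmarks): empty slab
    airway_mask(data, mask$spacing, mask$origin, z_top = zt, z_bottom = zb,
                region_tag = region)
  })
  names(out) <- names(bands)
  n_assigned <- sum(vapply(out, function(m) sum(m$data), numeric(1)))
  if (n_assigned != sum(mask$data))
    abort_data("partition does not cover the mask (%d of %d voxels assigned); crop the mask to [z(BEP), z(PNS)] first",
               n_assigned, sum(mask$data))
  structure(out, class = "region_partition")
}

#' Full segmentation chain for one reoriented scan
#'
#' Convenience wrapper running [threshold_air()], [crop_boundaries()],
#' [remove_islands()], [remove_dead_space()] and [partition_regions()].
#'
#' @param volume a reoriented [volume_image()].
#' @param landmarks a [landmark_set()] with PNS, TUV, TEP, BEP.
#' @param air_threshold HU threshold (default -400).
#' @param verbose log voxel counts per stage.
#' @return list with `mask` (total airway) and `partition`.
#' @export
segment_airway <- function(volume, landmarks, air_threshold = -400,
                           verbose = FALSE) {
  say <- function(stage, m) if (verbose)
    message(sprintf("  %-14s %9d voxels", stage, sum(m$data)))
  m <- threshold_air(volume, air_threshold); say("threshold", m)
  m <- crop_boundaries(m, landmark(landmarks, "PNS"), landmark(landmarks, "BEP"))
  say("crop", m)
  m <- remove_islands(m); say("islands", m)
  m <- remove_dead_space(m); say("dead_space", m)
  list(mask = m, partition = partition_regions(m, landmarks))
}
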