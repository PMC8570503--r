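# Core containers: volume_image (scalar HU grid), landmark_set (named mm
# points), airway_mask (binary lumen grid with boundary-plane heights) and
# region_partition (the four airway slabs).

#' Create a CT volume container
#'
#' A `volume_image` is a 3D scalar grid of Hounsfield units on an anisotropic
#' lattice. The internal frame is right-handed with +x left, +y anterior and
#' +z superior; world coordinates (mm) of voxel `(i, j, k)` (1-based) are
#' `origin + (c(i, j, k) - 1) * spacing`.
#'
#' @param data 3D numeric array of HU values.
#' @param spacing voxel spacing in mm, length-3 numeric (dx, dy, dz).
#' @param origin world coordinate (mm) of the center of voxel (1, 1, 1).
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(data, spacing, origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L) abort_validation("volume data must be a 3D array")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    abort_validation("spacing must be 3 positive finite numbers (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    abort_validation("origin must be 3 finite numbers (mm)")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_image> %d x %d x %d voxels, spacing %s mm, origin %s mm\n",
              d[1], d[2], d[3],
              paste(signif(x$spacing, 4), collapse = " x "),
              paste(signif(x$origin, 4), collapse = ", ")))
  invisible(x)
}

#' Create a named landmark set
#'
#' Landmarks are named 3D points in mm in the volume's frame. The canonical
#' airway names are `PNS`, `TUV`, `MUE`, `TEP`, `BEP` plus the Frankfort
#' fiducials `PO_L`, `PO_R` (left/right porion) and `OR` (orbitale).
#'
#' @param points numeric matrix with 3 columns (x, y, z in mm) and row names,
#'   or a named list of length-3 numeric vectors.
#' @return An object of class `landmark_set` (a named n x 3 matrix).
#' @export
landmark_set <- function(points) {
  if (is.list(points) && !is.matrix(points)) {
    nm <- names(points)
    points <- do.call(rbind, lapply(points, as.numeric))
    rownames(points) <- nm
  }
  points <- as.matrix(points)
  if (ncol(points) != 3L) abort_validation("landmarks must have 3 coordinates")
  if (is.null(rownames(points)) || anyNA(rownames(points)) || any(rownames(points) == ""))
    abort_validation("every landmark must be named")
  if (any(!is.finite(points))) abort_validation("landmark coordinates must be finite")
  colnames(points) <- c("x", "y", "z")
  structure(points, class = c("landmark_set", "matrix", "array"))
}

#' Extract one landmark as a length-3 vector
#' @param landmarks a [landmark_set()].
#' @param name landmark name.
#' @return numeric length-3 (x, y, z) in mm.
#' @export
landmark <- function(landmarks, name) {
  if (!name %in% rownames(landmarks))
    abort_validation("landmark '%s' is missing", name)
  as.numeric(landmarks[name, ])
}

#' Create an airway mask
#'
#' A binary voxel mask of the airway lumen on the lattice of its source
#' volume, together with the heights (mm) of the superior (`z_top`) and
#' inferior (`z_bottom`) boundary planes and a region tag.
#'
#' @param data 3D logical array.
#' @param spacing,origin lattice geometry as in [volume_image()].
#' @param z_top,z_bottom boundary plane heights in mm, `z_top > z_bottom`.
#' @param region_tag one of `"total"`, `"velopharynx"`, `"oropharynx"`,
#'   `"tongue_base"`, `"epiglottis"`.
#' @return An object of class `airway_mask`.
#' @export
airway_mask <- function(data, spacing, origin = c(0, 0, 0),
                        z_top = NULL, z_bottom = NULL, region_tag = "total") {
  if (length(dim(data)) != 3L) abort_validation("mask data must be a 3D array")
  storage.mode(data) <- "logical"
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  zc <- origin[3] + (seq_len(dim(data)[3]) - 1) * spacing[3]
  # default boundaries: the physical edges of the lattice (half a voxel
  # beyond the outermost slice centers); crop_boundaries() sets exact planes
  if (is.null(z_top)) z_top <- max(zc) + spacing[3] / 2
  if (is.null(z_bottom)) z_bottom <- min(zc) - spacing[3] / 2
  if (!isTRUE(z_top > z_bottom))
    abort_validation("z_top (%g) must exceed z_bottom (%g)", z_top, z_bottom)
  region_tag <- match.arg(region_tag, airway_regions())
  structure(list(data = data, spacing = spacing, origin = origin,
                 z_top = z_top, z_bottom = z_bottom, region_tag = region_tag),
            class = "airway_mask")
}

#' Canonical airway region tags, superior to inferior
#' @return character vector of the five region tags (total first).
#' @export
airway_regions <- function() {
  c("total", "velopharynx", "oropharynx", "tongue_base", "epiglottis")
}

#' @export
print.airway_mask <- function(x, ...) {
  cat(sprintf("<airway_mask:%s> %s voxels on %s grid, slab [%.2f, %.2f] mm\n",
              x$region_tag, format(sum(x$data), big.mark = ","),
              paste(dim(x$data), collapse = "x"), x$z_bottom, x$z_top))
  invisible(x)
}

# z coordinates (mm) of slice centers
slice_heights <- function(mask) {
  mask$origin[3] + (seq_len(dim(mask$data)[3]) - 1) * mask$spacing[3]
}

# indices of lattice slices whose centers lie within the boundary slab
slab_slices <- function(mask, tol = 1e-6) {
  z <- slice_heights(mask)
  which(z >= mask$z_bottom - tol & z <= mask$z_top + tol)
}

# world coordinates of voxel centers along each axis
axis_coords <- function(obj, axis) {
  obj$origin[axis] + (seq_len(dim(obj$data)[axis]) - 1) * obj$spacing[axis]
}
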