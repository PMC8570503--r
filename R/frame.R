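# Reference-frame handling: construction of the Frankfort Horizontal (FH)
# plane from cephalometric fiducials, reorientation of volumes and landmarks
# so that the FH plane is horizontal, the derived mid-uvula-epiglottis
# landmark, and rigid landmark-based superimposition of paired scans.

#' Construct the Frankfort Horizontal plane from three fiducials
#'
#' The conventional cephalometric definition uses both porions and the (left)
#' orbitale; any three non-collinear labeled points are accepted. The plane
#' normal is oriented toward superior (+z of the input frame).
#'
#' @param fiducials a [landmark_set()] or 3 x 3 matrix with three rows.
#' @return list with `point` (mm) and `unit_normal`, class `aw_plane`.
#' @export
construct_fh_plane <- function(fiducials) {
  p <- as.matrix(fiducials)
  if (nrow(p) != 3L) abort_validation("exactly three fiducials are required")
  v1 <- p[2, ] - p[1, ]; v2 <- p[3, ] - p[1, ]
  n <- c(v1[2] * v2[3] - v1[3] * v2[2],
         v1[3] * v2[1] - v1[1] * v2[3],
         v1[1] * v2[2] - v1[2] * v2[1])
  area2 <- sqrt(sum(n^2))
  if (area2 / 2 < 1e-6)
    abort_degenerate("fiducials are collinear (triangle area %.3g mm^2)", area2 / 2)
  n <- n / area2
  if (n[3] < 0) n <- -n
  structure(list(point = colMeans(p), unit_normal = as.numeric(n)),
            class = "aw_plane")
}

#' Midpoint landmark between uvula tip and epiglottis tip
#'
#' @param tuv,tep length-3 points in mm.
#' @return The componentwise midpoint (length-3 numeric).
#' @export
compute_mue <- function(tuv, tep) {
  tuv <- as.numeric(tuv); tep <- as.numeric(tep)
  if (isTRUE(all.equal(tuv, tep, tolerance = 0)) || all(tuv == tep))
    abort_degenerate("TUV and TEP coincide; midpoint undefined")
  (tuv + tep) / 2
}

#' Rigid transform constructor
#'
#' @param rotation 3x3 proper orthonormal matrix.
#' @param translation length-3 numeric (mm).
#' @return list of class `rigid_transform` with `rotation`, `translation`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (any(abs(crossprod(rotation) - diag(3)) > 1e-9))
    abort_validation("rotation must be orthonormal")
  if (abs(det(rotation) - 1) > 1e-9)
    abort_validation("rotation must be proper (det = +1)")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform to points
#' @param transform a [rigid_transform()].
#' @param points n x 3 matrix or length-3 vector (mm).
#' @return transformed points, same shape as the input.
#' @export
apply_transform <- function(transform, points) {
  vec <- is.null(dim(points))
  p <- if (vec) matrix(points, 1) else as.matrix(points)
  out <- p %*% t(transform$rotation) +
    matrix(transform$translation, nrow(p), 3, byrow = TRUE)
  if (vec) as.numeric(out) else {
    rownames(out) <- rownames(p)
    if (inherits(points, "landmark_set")) out <- landmark_set(out)
    out
  }
}

#' Invert a rigid transform
#' @param transform a [rigid_transform()].
#' @return the inverse [rigid_transform()].
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -as.numeric(Rt %*% transform$translation))
}

# rotation taking unit vector a onto unit vector b (Rodrigues)
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c0 <- sum(a * b)
  if (1 - c0 < 1e-15) return(diag(3))
  if (1 + c0 < 1e-12) { # opposite: rotate pi about any perpendicular axis
    perp <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- perp - sum(perp * a) * a; v <- v / sqrt(sum(v^2))
    return(2 * outer(v, v) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx / (1 + c0)
}

#' Reorient a volume so the Frankfort plane is horizontal
#'
#' Rotates the volume (about the plane's point) so the FH normal becomes +z,
#' resampling HU trilinearly onto a fresh axis-aligned lattice with the same
#' spacing; out-of-field voxels are filled with `fill` (soft tissue by
#' default, so no spurious air is created at the borders). Landmarks are
#' transformed consistently.
#'
#' @param volume a [volume_image()].
#' @param landmarks a [landmark_set()].
#' @param fh plane from [construct_fh_plane()].
#' @param fill HU value for voxels mapped from outside the input field.
#' @param method `"trilinear"` (HU volumes) or `"nearest"` (label volumes).
#' @return list with `volume`, `landmarks` and the applied `transform`.
#' @export
reorient <- function(volume, landmarks, fh, fill = 40,
                     method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  rot <- rotation_between(fh$unit_normal, c(0, 0, 1))
  p0 <- fh$point
  tf <- rigid_transform(rot, as.numeric(p0 - rot %*% p0))

  d <- dim(volume$data)
  corners <- as.matrix(expand.grid(
    x = volume$origin[1] + c(0, d[1] - 1) * volume$spacing[1],
    y = volume$origin[2] + c(0, d[2] - 1) * volume$spacing[2],
    z = volume$origin[3] + c(0, d[3] - 1) * volume$spacing[3]))
  tc <- apply_transform(tf, corners)
  lo <- apply(tc, 2, min); hi <- apply(tc, 2, max)
  out_dims <- as.integer(ceiling((hi - lo) / volume$spacing)) + 1L
  out_origin <- lo

  inv <- invert_transform(tf)
  M <- cbind(inv$rotation, inv$translation)
  arr <- .cpp_resample_rigid(
    as.numeric(volume$data), dim(volume$data), volume$spacing, volume$origin,
    M, out_dims, volume$spacing, out_origin,
    if (method == "nearest") 1L else 0L, fill)
  dim(arr) <- out_dims
  list(volume = volume_image(arr, volume$spacing, out_origin),
       landmarks = apply_transform(tf, landmarks),
       transform = tf)
}

#' Least-squares rigid superimposition of labeled point sets
#'
#' Solves the orthogonal Procrustes problem (Kabsch): the proper rigid
#' transform (rotation plus translation, no scaling, det = +1) minimizing the
#' sum of squared distances between transformed moving points and their
#' fixed counterparts. Stands in for voxel-based cranial-base registration
#' when exact fiducials are available.
#'
#' @param moving,fixed n x 3 matrices (n >= 3) with matching row order, or
#'   [landmark_set()]s sharing names (matched by name).
#' @return A [rigid_transform()] mapping moving onto fixed.
#' @export
superimpose <- function(moving, fixed) {
  m <- as.matrix(moving); f <- as.matrix(fixed)
  if (!is.null(rownames(m)) && !is.null(rownames(f))) {
    common <- intersect(rownames(m), rownames(f))
    if (length(common) >= 3) { m <- m[common, , drop = FALSE]; f <- f[common, , drop = FALSE] }
  }
  if (nrow(m) < 3 || nrow(m) != nrow(f))
    abort_degenerate("at least 3 corresponding points are required")
  cm <- colMeans(m); cf <- colMeans(f)
  mc <- sweep(m, 2, cm); fc <- sweep(f, 2, cf)
  if (svd(mc)$d[2] < 1e-9 * max(svd(mc)$d[1], 1))
    abort_degenerate("points are collinear; rotation is not identifiable")
  H <- t(mc) %*% fc
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rigid_transform(rot, as.numeric(cf - rot %*% cm))
}
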