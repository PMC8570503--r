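# Geometric fixtures built in code: voxelized primitives and small phantom
# specs shared across test files.

# voxelized ball of radius r (mm), isotropic spacing h, centered in the grid
ball_mask <- function(r, h, pad = 4) {
  n <- ceiling(2 * r / h) + 2 * pad + 1
  cs <- (seq_len(n) - (n + 1) / 2) * h
  arr <- array(outer(outer(cs^2, cs^2, `+`), cs^2, `+`) <= r^2, c(n, n, n))
  airway_mask(arr, rep(h, 3), origin = rep(cs[1], 3))
}

# voxelized z-aligned cylinder: radius r, length L (slab [0, L]), spacing h
cylinder_mask <- function(r, L, h, pad = 4) {
  nxy <- ceiling(2 * r / h) + 2 * pad + 1
  cs <- (seq_len(nxy) - (nxy + 1) / 2) * h
  nz <- ceiling(L / h) + 2 * pad
  zs <- (seq_len(nz) - 1) * h - pad * h + h / 2
  inplane <- outer(cs^2, cs^2, `+`) <= r^2
  arr <- array(FALSE, c(nxy, nxy, nz))
  zin <- zs > 0 & zs < L
  for (k in which(zin)) arr[, , k] <- inplane
  airway_mask(arr, rep(h, 3), origin = c(cs[1], cs[1], zs[1]),
              z_top = L, z_bottom = 0)
}

# constant circular tube spec (area pi r^2, LAT/AP = 1)
tube_spec <- function(r = 8, L = 60, spacing = 0.5, noise_sd = 0,
                      fracs = c(TUV = 0.25, TEP = 0.75, BEP = 1.0), ...) {
  phantom_spec(axis_length = L,
               area_profile = function(t) rep(pi * r^2, length(t)),
               ellipse_ratio_profile = function(t) rep(1, length(t)),
               landmark_fracs = fracs,
               noise_sd = noise_sd, voxel_spacing = rep(spacing, 3), ...)
}

# tube with a Gaussian constriction down to area `a_min` at fraction `at`
constricted_spec <- function(a_base = 220, a_min = 80, at = 0.6, L = 66,
                             spacing = 0.5, noise_sd = 0, ratio = 2.6,
                             width = 0.16, ...) {
  phantom_spec(axis_length = L,
               area_profile = function(t)
                 a_base - (a_base - a_min) * exp(-((t / L - at) / width)^2),
               ellipse_ratio_profile = function(t) rep(ratio, length(t)),
               noise_sd = noise_sd, voxel_spacing = rep(spacing, 3), ...)
}

# voxelize the analytic lumen of a spec on the lattice of a made phantom
# (the reference set for Dice / threshold-equality checks)
lumen_voxels <- function(spec, volume) {
  d <- dim(volume$data)
  xs <- volume$origin[1] + (seq_len(d[1]) - 1) * volume$spacing[1]
  ys <- volume$origin[2] + (seq_len(d[2]) - 1) * volume$spacing[2]
  zs <- volume$origin[3] + (seq_len(d[3]) - 1) * volume$spacing[3]
  arr <- array(FALSE, d)
  for (k in seq_len(d[3])) {
    s <- airwaymorph:::lumen_semiaxes(spec, spec$axis_length - zs[k])
    arr[, , k] <- outer((xs / s$a)^2, ((ys - s$cy) / s$b)^2, `+`) <= 1
  }
  arr
}

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

expect_aw_error <- function(expr, class) {
  testthat::expect_error(expr, class = class)
}
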