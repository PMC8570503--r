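# Synthetic airway phantoms. The phantom is an air-filled tube of elliptical
# cross-section embedded in a soft-tissue block, with optional re-entrant
# pockets (mouth / vallecular dead space), disconnected air blobs (islands),
# landmarks placed on the geometry, and a paired-scan perturbation model.
# Geometry is analytic, so every morphometric parameter has a quadrature
# ground truth that is independent of any voxelization.

#' Specify a synthetic airway phantom
#'
#' The lumen axis runs superior to inferior. The along-axis coordinate `t`
#' (mm) is 0 at the PNS plane and `axis_length` at the inferior end of the
#' modeled segment; world height is `z = axis_length - t` so that the BEP
#' plane sits at `z = axis_length * (1 - frac_BEP)`.
#'
#' @param axis_length distance (mm) from the PNS plane to the end of the
#'   modeled axis; the BEP plane lies at `landmark_fracs["BEP"] * axis_length`.
#' @param area_profile vectorized function `t (mm) -> area (mm^2)` giving the
#'   lumen cross-sectional area; must be strictly positive on
#'   `[0, axis_length]`. Values outside that interval are clamped.
#' @param ellipse_ratio_profile vectorized function `t -> LAT/AP` ratio of the
#'   elliptical cross-section (lateral semi-axis over anteroposterior).
#' @param bend_profile vectorized function `t -> y offset (mm)` of the lumen
#'   center line (anterior bowing); default is straight.
#' @param landmark_fracs named numeric, fractions of `axis_length` at which
#'   TUV, TEP and BEP sit; requires `0 < TUV < TEP < BEP <= 1`.
#' @param pockets list of dead-space pockets, each
#'   `list(center = c(x, y, z) mm, radius = mm, attachment = label)`. Pockets
#'   are spheres connected to the lumen only through a thin channel at the
#'   pocket bottom, i.e. they open upward and are reached from the lumen by a
#'   re-ascending path (like the mouth and the valleculae).
#' @param islands list of disconnected air blobs, each
#'   `list(center = c(x, y, z) mm, radius = mm)`; must not touch the lumen or
#'   any pocket.
#' @param hu_air,hu_tissue Hounsfield values of air and soft tissue.
#' @param noise_sd standard deviation (HU) of additive Gaussian noise.
#' @param voxel_spacing voxel spacing in mm (dx, dy, dz).
#' @param pns_y_offset anterior offset (mm) of the PNS landmark relative to
#'   the anterior lumen wall at `t = 0`; the anterior crop plane of
#'   [crop_boundaries()] passes through this y.
#' @param channel_radius radius (mm) of pocket attachment channels.
#' @param xy_margin,z_margin tissue margins (mm) around the modeled geometry.
#' @return An object of class `phantom_spec`.
#' @seealso [make_phantom()], [analytic_truth()], [perturb_phantom()]
#' @export
phantom_spec <- function(axis_length = 66,
                         area_profile = function(t) rep(220, length(t)),
                         ellipse_ratio_profile = function(t) rep(2.6, length(t)),
                         bend_profile = function(t) rep(0, length(t)),
                         landmark_fracs = c(TUV = 0.505, TEP = 0.758, BEP = 1.0),
                         pockets = list(),
                         islands = list(),
                         hu_air = -1000, hu_tissue = 40, noise_sd = 10,
                         voxel_spacing = c(0.5, 0.5, 0.5),
                         pns_y_offset = 20,
                         channel_radius = 1.5,
                         xy_margin = 4, z_margin = 4) {
  spec <- structure(list(
    axis_length = axis_length,
    area_profile = area_profile,
    ellipse_ratio_profile = ellipse_ratio_profile,
    bend_profile = bend_profile,
    landmark_fracs = landmark_fracs,
    pockets = pockets, islands = islands,
    hu_air = hu_air, hu_tissue = hu_tissue, noise_sd = noise_sd,
    voxel_spacing = as.numeric(voxel_spacing),
    pns_y_offset = pns_y_offset,
    channel_radius = channel_radius,
    xy_margin = xy_margin, z_margin = z_margin), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

# lumen semi-axes at t: lateral a, anteroposterior b (area = pi * a * b)
lumen_semiaxes <- function(spec, t) {
  t <- pmin(pmax(t, 0), spec$axis_length)
  A <- spec$area_profile(t)
  r <- spec$ellipse_ratio_profile(t)
  list(a = sqrt(A * r / pi), b = sqrt(A / (pi * r)), A = A, r = r,
       cy = spec$bend_profile(t))
}

#' Validate a phantom specification
#'
#' Checks the spec invariants: positive area profile, strictly increasing
#' landmark fractions, pockets clear of the lumen, and islands clear of both
#' lumen and pockets. Violations raise a classed validation error naming the
#' violated invariant.
#'
#' @param spec a [phantom_spec()].
#' @return `spec`, invisibly.
#' @export
validate_phantom_spec <- function(spec) {
  L <- spec$axis_length
  if (!is.finite(L) || L <= 0) abort_validation("axis_length must be positive")
  tg <- seq(0, L, length.out = 1001)
  if (any(!is.finite(spec$area_profile(tg))) || any(spec$area_profile(tg) <= 0))
    abort_validation("invariant violated: area_profile(t) > 0 on [0, axis_length]")
  if (any(spec$ellipse_ratio_profile(tg) <= 0))
    abort_validation("ellipse_ratio_profile must be positive")
  f <- spec$landmark_fracs
  if (!all(c("TUV", "TEP", "BEP") %in% names(f)))
    abort_validation("landmark_fracs must name TUV, TEP and BEP")
  if (!(0 < f[["TUV"]] && f[["TUV"]] < f[["TEP"]] &&
        f[["TEP"]] < f[["BEP"]] && f[["BEP"]] <= 1))
    abort_validation(
      "invariant violated: landmark fractions must satisfy 0 < frac(TUV) < frac(TEP) < frac(BEP) <= 1")
  if (any(spec$voxel_spacing <= 0)) abort_validation("voxel_spacing must be positive")
  if (spec$noise_sd < 0) abort_validation("noise_sd must be non-negative")
  if (spec$hu_air >= spec$hu_tissue)
    abort_validation("hu_air must be below hu_tissue")
  gap <- max(spec$voxel_spacing)
  for (p in spec$pockets) {
    if (lumen_clearance(spec, p$center, p$radius) < gap)
      abort_validation("invariant violated: pocket at (%s) intrudes into the lumen",
                       paste(signif(p$center, 3), collapse = ", "))
  }
  for (isl in spec$islands) {
    if (point_in_lumen(spec, isl$center) || point_in_pockets(spec, isl$center))
      abort_validation(
        "invariant violated: island center (%s) must lie strictly outside the lumen and pockets",
        paste(signif(isl$center, 3), collapse = ", "))
    if (lumen_clearance(spec, isl$center, isl$radius) < gap)
      abort_validation("invariant violated: island at (%s) touches the lumen",
                       paste(signif(isl$center, 3), collapse = ", "))
    for (p in spec$pockets) {
      d <- sqrt(sum((isl$center - p$center)^2))
      if (d < isl$radius + p$radius + spec$channel_radius + gap)
        abort_validation("invariant violated: island at (%s) touches a pocket",
                         paste(signif(isl$center, 3), collapse = ", "))
    }
  }
  invisible(spec)
}

point_in_lumen <- function(spec, pt) {
  t <- spec$axis_length - pt[3]
  s <- lumen_semiaxes(spec, t)
  (pt[1] / s$a)^2 + ((pt[2] - s$cy) / s$b)^2 <= 1
}

point_in_pockets <- function(spec, pt) {
  for (p in spec$pockets)
    if (sum((pt - p$center)^2) <= p$radius^2) return(TRUE)
  FALSE
}

# smallest distance from a sphere (center, radius) to the lumen surface,
# negative if intersecting; numeric check on a theta x z sampling grid
lumen_clearance <- function(spec, center, radius) {
  zs <- seq(center[3] - radius, center[3] + radius, length.out = 41)
  theta <- seq(0, 2 * pi, length.out = 257)[-257]
  best <- Inf
  for (z in zs) {
    rho <- sqrt(max(radius^2 - (z - center[3])^2, 0))
    s <- lumen_semiaxes(spec, spec$axis_length - z)
    ex <- s$a * cos(theta); ey <- s$cy + s$b * sin(theta)
    d <- sqrt((ex - center[1])^2 + (ey - center[2])^2)
    inside_c <- (center[1] / s$a)^2 + ((center[2] - s$cy) / s$b)^2 <= 1
    clear <- if (inside_c) -Inf else min(d) - rho
    best <- min(best, clear)
  }
  best
}

#' Default airway phantom
#'
#' A ready-made `phantom_spec` emulating an adult upper airway: 66 mm axis, a
#' baseline cross-section of 220 mm^2 constricted to 80 mm^2 by a Gaussian
#' narrowing, lateral-to-anteroposterior ratio 2.6, an anterior "mouth"
#' pocket, a vallecular pocket, and two disconnected air islands.
#'
#' @param voxel_spacing voxel spacing mm, default 0.5 isotropic.
#' @param noise_sd HU noise, default 10 (0 gives a noise-free phantom).
#' @param with_pockets,with_islands include dead-space pockets / islands.
#' @param constriction_area minimum cross-sectional area (mm^2) of the
#'   narrowing (default 80).
#' @param constriction_frac position of the narrowing as a fraction of the
#'   axis (default 0.60, in the oropharynx).
#' @return A `phantom_spec`.
#' @export
default_phantom_spec <- function(voxel_spacing = c(0.5, 0.5, 0.5),
                                 noise_sd = 10,
                                 with_pockets = TRUE, with_islands = TRUE,
                                 constriction_area = 80,
                                 constriction_frac = 0.60) {
  L <- 66
  base <- 220
  depth <- base - constriction_area
  ap <- function(t) base - depth * exp(-((t / L - constriction_frac) / 0.16)^2)
  pockets <- if (with_pockets) list(
    list(center = c(0, 18, L * (1 - 0.57)), radius = 6, attachment = "mouth"),
    list(center = c(0, 12, L * (1 - 0.78)), radius = 4, attachment = "vallecula")
  ) else list()
  islands <- if (with_islands) list(
    list(center = c(15, -8, 30), radius = 2.5),
    list(center = c(-16, -10, 50), radius = 2)
  ) else list()
  phantom_spec(axis_length = L, area_profile = ap,
               ellipse_ratio_profile = function(t) rep(2.6, length(t)),
               landmark_fracs = c(TUV = 0.505, TEP = 0.758, BEP = 1.0),
               pockets = pockets, islands = islands,
               noise_sd = noise_sd, voxel_spacing = voxel_spacing)
}

# two independent sub-seeds (geometry stream, noise stream) from one seed
phantom_streams <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  sample.int(2147483646L, 2L)
}

#' Voxelize a phantom into a CT volume with landmarks and ground truth
#'
#' Renders the phantom geometry onto a regular voxel lattice: HU `hu_air`
#' inside the lumen, pockets and islands, `hu_tissue` elsewhere, plus
#' Gaussian noise. Landmarks lie on the geometry: PNS at the superior lumen
#' entry (offset anteriorly by `pns_y_offset`), TUV/TEP/BEP on the anterior
#' lumen wall at their fractional heights, and three Frankfort fiducials
#' (PO_L, PO_R, OR) spanning a horizontal plane. Identical `(spec, seed)`
#' give bit-identical output.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed; drives the noise stream only (the geometry is
#'   deterministic given `spec`).
#' @return list with elements `volume` ([volume_image()]), `landmarks`
#'   ([landmark_set()]) and `truth` (the [analytic_truth()] of `spec`).
#' @export
make_phantom <- function(spec, seed = 1L) {
  validate_phantom_spec(spec)
  L <- spec$axis_length
  h <- spec$voxel_spacing
  f <- spec$landmark_fracs
  z_bep <- L * (1 - f[["BEP"]])

  tg <- seq(0, L, length.out = 513)
  sg <- lumen_semiaxes(spec, tg)
  xmax <- max(sg$a) + spec$xy_margin
  ylo <- min(sg$cy - sg$b) - spec$xy_margin
  yhi <- max(sg$cy + sg$b) + spec$xy_margin
  y_pns <- sg$cy[1] + sg$b[1] + spec$pns_y_offset
  yhi <- max(yhi, y_pns + 2)
  zlo <- z_bep - spec$z_margin
  zhi <- L + spec$z_margin
  for (obj in c(spec$pockets, spec$islands)) {
    xmax <- max(xmax, abs(obj$center[1]) + obj$radius + spec$xy_margin)
    ylo <- min(ylo, obj$center[2] - obj$radius - spec$xy_margin)
    yhi <- max(yhi, obj$center[2] + obj$radius + spec$xy_margin)
  }

  nx <- ceiling(2 * xmax / h[1]) + 1
  ny <- ceiling((yhi - ylo) / h[2]) + 1
  nz <- ceiling((zhi - zlo) / h[3]) + 1
  origin <- c(-xmax, ylo, zlo)
  xs <- origin[1] + (seq_len(nx) - 1) * h[1]
  ys <- origin[2] + (seq_len(ny) - 1) * h[2]
  zs <- origin[3] + (seq_len(nz) - 1) * h[3]

  air <- array(FALSE, c(nx, ny, nz))
  for (k in seq_len(nz)) {
    z <- zs[k]
    s <- lumen_semiaxes(spec, L - z)
    slice <- outer((xs / s$a)^2, ((ys - s$cy) / s$b)^2, `+`) <= 1
    for (p in spec$pockets) {
      dz2 <- p$radius^2 - (z - p$center[3])^2
      if (dz2 > 0)
        slice <- slice | (outer((xs - p$center[1])^2, (ys - p$center[2])^2, `+`) <= dz2)
      z_att <- p$center[3] - p$radius
      cr <- min(spec$channel_radius, p$radius / 2)
      w2 <- cr^2 - (z - z_att)^2
      if (w2 > 0) {
        xo <- abs(xs - p$center[1]) <= sqrt(w2)
        yr <- range(c(s$cy, p$center[2]))
        yo <- ys >= yr[1] & ys <= yr[2]
        slice <- slice | outer(xo, yo, `&`)
      }
    }
    for (isl in spec$islands) {
      dz2 <- isl$radius^2 - (z - isl$center[3])^2
      if (dz2 > 0)
        slice <- slice | (outer((xs - isl$center[1])^2, (ys - isl$center[2])^2, `+`) <= dz2)
    }
    air[, , k] <- slice
  }

  hu <- array(spec$hu_tissue, dim(air))
  hu[air] <- spec$hu_air
  if (spec$noise_sd > 0) {
    streams <- phantom_streams(seed)
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(streams[2], kind = "Mersenne-Twister", normal.kind = "Inversion")
    hu <- hu + array(rnorm(length(hu), 0, spec$noise_sd), dim(hu))
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }

  t_lm <- c(TUV = f[["TUV"]], TEP = f[["TEP"]], BEP = f[["BEP"]]) * L
  s_lm <- lumen_semiaxes(spec, t_lm)
  lms <- rbind(
    PNS  = c(0, y_pns, L),
    TUV  = c(0, s_lm$cy[1] + s_lm$b[1], L - t_lm[["TUV"]]),
    TEP  = c(0, s_lm$cy[2] + s_lm$b[2], L - t_lm[["TEP"]]),
    BEP  = c(0, s_lm$cy[3] + s_lm$b[3], L - t_lm[["BEP"]]),
    PO_L = c(-45, -30, L + 8),
    PO_R = c(45, -30, L + 8),
    OR   = c(0, 35, L + 8))

  list(volume = volume_image(hu, h, origin),
       landmarks = landmark_set(lms),
       truth = analytic_truth(spec))
}

#' Perturb a phantom to emulate a second acquisition
#'
#' Emulates the intra-individual variation between two scans of the same
#' subject (posture, tongue position, breathing stage): the area profile is
#' multiplied by a smooth random field confined to `[1 - amp, 1 + amp]` with
#' unit mean over random phases, the soft-tissue landmark fractions (TUV,
#' TEP, BEP) are jittered, and the lumen center line may bow anteriorly.
#' PNS is a bony landmark and is never moved, mirroring its once-only
#' localization at the first time point.
#'
#' @param spec a [phantom_spec()] (the T0 anatomy).
#' @param perturbation list with `area_scale_amp` (fraction, >= 0),
#'   `landmark_jitter_sd` (mm) and `axis_bend_amp` (mm).
#' @param seed integer seed for the perturbation draws.
#' @return A new `phantom_spec` (the T1 anatomy). All-zero amplitudes return
#'   `spec` unchanged.
#' @export
perturb_phantom <- function(spec,
                            perturbation = list(area_scale_amp = 0.15,
                                                landmark_jitter_sd = 1.0,
                                                axis_bend_amp = 1.0),
                            seed = 1L) {
  validate_phantom_spec(spec)
  amp <- perturbation$area_scale_amp %||% 0
  jit <- perturbation$landmark_jitter_sd %||% 0
  bend <- perturbation$axis_bend_amp %||% 0
  if (any(c(amp, jit, bend) < 0))
    abort_validation("perturbation amplitudes must be non-negative")
  if (amp == 0 && jit == 0 && bend == 0) return(spec)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(phantom_streams(seed)[1], kind = "Mersenne-Twister",
           normal.kind = "Inversion")

  out <- spec
  L <- spec$axis_length
  if (amp > 0) {
    k <- sample(c(0.5, 1, 1.5, 2), 1)
    phi <- runif(1, 0, 2 * pi)
    base_area <- spec$area_profile
    out$area_profile <- function(t) {
      t <- pmin(pmax(t, 0), L)
      base_area(t) * (1 + amp * sin(2 * pi * k * t / L + phi))
    }
  }
  if (jit > 0) {
    f <- spec$landmark_fracs
    ok <- FALSE
    for (i in seq_len(1000)) {
      cand <- f
      cand[c("TUV", "TEP", "BEP")] <-
        f[c("TUV", "TEP", "BEP")] + rnorm(3, 0, jit / L)
      if (0 < cand[["TUV"]] && cand[["TUV"]] < cand[["TEP"]] &&
          cand[["TEP"]] < cand[["BEP"]] && cand[["BEP"]] <= 1) {
        out$landmark_fracs <- cand; ok <- TRUE; break
      }
    }
    if (!ok) abort_validation("landmark jitter too large for the axis: ordering cannot be preserved")
  }
  if (bend > 0) {
    w <- runif(1, -1, 1)
    base_bend <- spec$bend_profile
    out$bend_profile <- function(t) {
      t <- pmin(pmax(t, 0), L)
      base_bend(t) + bend * w * sin(pi * t / L)
    }
  }
  validate_phantom_spec(out)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# composite Simpson integral of fn over [lo, hi] with n intervals (even)
simpson <- function(fn, lo, hi, n = 4096L) {
  if (hi <= lo) return(0)
  n <- if (n %% 2L == 1L) n + 1L else n
  x <- seq(lo, hi, length.out = n + 1L)
  w <- c(1, rep(c(4, 2), length.out = n - 1L), 1)
  sum(w * fn(x)) * (hi - lo) / (3 * n)
}

#' Analytic ground-truth parameters of a phantom
#'
#' Computes the morphometric parameters of the clean lumen (pockets and
#' islands are by definition not part of the airway) for the total airway and
#' the four landmark-bounded regions, by quadrature on the analytic geometry:
#' volume as the integral of the area profile, surface as the lateral surface
#' integral of the elliptical tube plus planar caps, the minimum
#' cross-sectional area by profile minimization, and the derived parameters
#' from their defining formulas.
#'
#' @param spec a [phantom_spec()].
#' @return A data frame of class `phantom_truth` with one row per region
#'   (total, velopharynx, oropharynx, tongue_base, epiglottis) and the same
#'   columns as [measure_airway()].
#' @export
analytic_truth <- function(spec) {
  validate_phantom_spec(spec)
  L <- spec$axis_length
  f <- spec$landmark_fracs
  mue <- (f[["TUV"]] + f[["TEP"]]) / 2
  bounds <- list(
    total       = c(0, f[["BEP"]]),
    velopharynx = c(0, f[["TUV"]]),
    oropharynx  = c(f[["TUV"]], mue),
    tongue_base = c(mue, f[["TEP"]]),
    epiglottis  = c(f[["TEP"]], f[["BEP"]]))

  area <- function(t) spec$area_profile(pmin(pmax(t, 0), L))
  eps <- L * 1e-5
  semi <- function(t) lumen_semiaxes(spec, t)
  lateral_integrand <- function(theta, t) {
    s0 <- semi(t); sp <- semi(t + eps); sm <- semi(t - eps)
    da <- (sp$a - sm$a) / (2 * eps)
    db <- (sp$b - sm$b) / (2 * eps)
    dc <- (sp$cy - sm$cy) / (2 * eps)
    ct <- cos(theta); st <- sin(theta)
    a <- rep(s0$a, each = length(theta)); b <- rep(s0$b, each = length(theta))
    da <- rep(da, each = length(theta)); db <- rep(db, each = length(theta))
    dc <- rep(dc, each = length(theta))
    ct <- rep(ct, times = length(t)); st <- rep(st, times = length(t))
    sqrt((b * ct)^2 + (a * st)^2 + (a * st * (dc + db * st) + da * b * ct^2)^2)
  }

  rows <- lapply(names(bounds), function(region) {
    lo <- bounds[[region]][1] * L
    hi <- bounds[[region]][2] * L
    len <- hi - lo
    V <- simpson(area, lo, hi)

    tg <- seq(lo, hi, length.out = 4097)
    Ag <- area(tg)
    i0 <- which.min(Ag)
    lo_o <- max(lo, tg[max(i0 - 2, 1)]); hi_o <- min(hi, tg[min(i0 + 2, length(tg))])
    opt <- if (hi_o > lo_o) optimize(area, c(lo_o, hi_o), tol = 1e-9) else
      list(minimum = tg[i0], objective = Ag[i0])
    if (opt$objective <= Ag[i0]) {
      t_mca <- opt$minimum; MCA <- opt$objective
    } else {
      t_mca <- tg[i0]; MCA <- Ag[i0]
    }
    s_mca <- semi(t_mca)
    LAT <- 2 * s_mca$a; AP <- 2 * s_mca$b

    nt <- 2048L
    tq <- seq(lo, hi, length.out = nt + 1L)
    theta <- seq(0, 2 * pi, length.out = 513L)[-513L]
    g <- lateral_integrand(theta, tq)
    dim(g) <- c(length(theta), length(tq))
    per_t <- colSums(g) * (2 * pi / length(theta))
    wt <- c(1, rep(c(4, 2), length.out = nt - 1L), 1)
    SA <- sum(wt * per_t) * len / (3 * nt)
    SA_closed <- SA + area(lo) + area(hi)

    dp <- derive_parameters(V = V, L = len, SA_closed = SA_closed,
                            MCA = MCA, LAT = LAT, AP = AP)
    data.frame(region = region, V = V, L = len, SA = SA, SA_closed = SA_closed,
               MCA = MCA, MCA_z = L - t_mca, LAT = LAT, AP = AP,
               meanCSA = dp$meanCSA, lat_ap_ratio = dp$lat_ap_ratio,
               uniformity = dp$uniformity, sphericity = dp$sphericity,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("phantom_truth", "airway_parameters", "data.frame")
  out
}

#' Generate a paired-scan phantom cohort
#'
#' Emulates a test-retest study population: each subject gets an individual
#' anatomy (a between-subject perturbation of `base_spec`) and a pair of
#' specs T0/T1 separated by a within-subject perturbation. Use
#' [analytic_truth()] or the full voxel pipeline on each pair.
#'
#' @param n_subjects number of subjects.
#' @param base_spec cohort base anatomy, default [default_phantom_spec()].
#' @param between perturbation list for between-subject anatomy differences.
#' @param within perturbation list for the T0 to T1 change.
#' @param seed integer master seed.
#' @return list of `n_subjects` elements, each
#'   `list(subject_id, spec_t0, spec_t1)`.
#' @export
make_paired_cohort <- function(n_subjects = 10,
                               base_spec = default_phantom_spec(),
                               between = list(area_scale_amp = 0.25,
                                              landmark_jitter_sd = 2.5,
                                              axis_bend_amp = 2.0),
                               within = list(area_scale_amp = 0.15,
                                             landmark_jitter_sd = 1.0,
                                             axis_bend_amp = 1.0),
                               seed = 1L) {
  lapply(seq_len(n_subjects), function(i) {
    s0 <- perturb_phantom(base_spec, between, seed = seed * 1000L + i)
    s1 <- perturb_phantom(s0, within, seed = seed * 1000L + 500L + i)
    list(subject_id = sprintf("S%02d", i), spec_t0 = s0, spec_t1 = s1)
  })
}
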