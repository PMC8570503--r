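# Between-scan variation statistics: relative difference, intraclass
# correlation (two-way random / mixed and one-way variants for k = 2
# measurements), Bland-Altman agreement, smallest detectable difference, and
# the cohort summary table (one row per parameter x region).

#' Relative difference between paired values, in percent
#'
#' `100 * |a - b| / ((a + b) / 2)`: symmetric in its arguments and invariant
#' to rescaling both by the same positive constant. Vectorized.
#'
#' @param a,b numeric vectors of paired measurements.
#' @return percent relative difference(s).
#' @export
relative_difference <- function(a, b) {
  m <- (a + b) / 2
  if (any(m == 0)) abort_undefined_statistic("relative difference undefined: pair mean is zero")
  100 * abs(a - b) / abs(m)
}

#' Intraclass correlation coefficient for paired measurements
#'
#' Computes the single-measurement ICC from a two-column layout (n subjects,
#' k = 2 measurements). The default, ICC(2,1), is the two-way random-effects
#' absolute-agreement coefficient, appropriate when the two measurements
#' should be interchangeable; ICC(3,1) (two-way mixed, consistency) and
#' ICC(1,1) (one-way random) are selectable.
#'
#' Reliability classes follow the Fleiss benchmarks: poor below 0.40, fair
#' to good between 0.40 and 0.75, excellent above 0.75. Values exactly on a
#' boundary are assigned to the lower class.
#'
#' @param t0,t1 numeric vectors of paired measurements (same length, n >= 2).
#' @param model `"icc2_1"` (default), `"icc3_1"` or `"icc1_1"`.
#' @return list with `icc`, `icc_class` and `model`.
#' @export
icc <- function(t0, t1, model = c("icc2_1", "icc3_1", "icc1_1")) {
  model <- match.arg(model)
  if (length(t0) != length(t1)) abort_validation("t0 and t1 must have equal length")
  n <- length(t0)
  if (n < 2) abort_sample_size("ICC requires at least 2 subjects")
  if (any(!is.finite(c(t0, t1)))) abort_data("ICC inputs must be finite")
  x <- cbind(t0, t1)
  k <- 2
  gm <- mean(x)
  if (sum((x - gm)^2) < 1e-12 * max(1, gm^2))
    abort_undefined_statistic("ICC undefined: total variance is zero")
  rowm <- rowMeans(x); colm <- colMeans(x)
  SSR <- k * sum((rowm - gm)^2)
  SSC <- n * sum((colm - gm)^2)
  SST <- sum((x - gm)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  val <- switch(model,
    icc2_1 = {
      den <- MSR + (k - 1) * MSE + (k / n) * (MSC - MSE)
      if (abs(den) < 1e-300) abort_undefined_statistic("ICC undefined: zero denominator")
      (MSR - MSE) / den
    },
    icc3_1 = {
      den <- MSR + (k - 1) * MSE
      if (abs(den) < 1e-300) abort_undefined_statistic("ICC undefined: zero denominator")
      (MSR - MSE) / den
    },
    icc1_1 = {
      MSW <- (SSC + SSE) / (n * (k - 1))
      den <- MSR + (k - 1) * MSW
      if (abs(den) < 1e-300) abort_undefined_statistic("ICC undefined: zero denominator")
      (MSR - MSW) / den
    })
  list(icc = val, icc_class = icc_class(val), model = model)
}

icc_class <- function(icc) {
  if (!is.finite(icc)) return(NA_character_)
  if (icc <= 0.40) "poor" else if (icc <= 0.75) "fair to good" else "excellent"
}

#' Bland-Altman agreement analysis of paired measurements
#'
#' Differences are `d = t0 - t1`; the standard deviation uses the sample
#' (n - 1) denominator and the limits of agreement are
#' `mean(d) +/- 1.96 * sd(d)` with the conventional fixed 1.96 multiplier.
#'
#' @param t0,t1 numeric vectors of paired measurements (n >= 2).
#' @return list with `diff_mean`, `diff_sd`, `loa_upper`, `loa_lower`.
#' @export
bland_altman <- function(t0, t1) {
  if (length(t0) != length(t1)) abort_validation("t0 and t1 must have equal length")
  if (length(t0) < 2) abort_sample_size("Bland-Altman requires at least 2 pairs")
  d <- t0 - t1
  loa_from_stats(mean(d), sd(d))
}

#' Bland-Altman limits from a printed difference mean and SD
#'
#' Desk-calculation entry point: reproduces limits of agreement from summary
#' statistics alone.
#'
#' @param diff_mean mean of paired differences.
#' @param diff_sd sample SD of paired differences.
#' @return list with `diff_mean`, `diff_sd`, `loa_upper`, `loa_lower`.
#' @export
loa_from_stats <- function(diff_mean, diff_sd) {
  if (diff_sd < 0) abort_validation("diff_sd must be non-negative")
  list(diff_mean = diff_mean, diff_sd = diff_sd,
       loa_upper = diff_mean + 1.96 * diff_sd,
       loa_lower = diff_mean - 1.96 * diff_sd)
}

#' Smallest detectable difference
#'
#' `SDD = 1.96 * SD(t0 - t1)`: the change a repeated measurement must exceed
#' to be considered a real change rather than test-retest noise.
#'
#' @param t0,t1 numeric vectors of paired measurements (n >= 2).
#' @return SDD on the scale of the measurements.
#' @export
sdd <- function(t0, t1) {
  if (length(t0) != length(t1)) abort_validation("t0 and t1 must have equal length")
  if (length(t0) < 2) abort_sample_size("SDD requires at least 2 pairs")
  sdd_from_sd(sd(t0 - t1))
}

#' Smallest detectable difference from a printed difference SD
#' @param diff_sd sample SD of paired differences.
#' @return `1.96 * diff_sd`.
#' @export
sdd_from_sd <- function(diff_sd) {
  if (diff_sd < 0) abort_validation("diff_sd must be non-negative")
  1.96 * diff_sd
}

#' Canonical report parameters
#' @return the ten parameter tags of the cohort report, in table order.
#' @export
report_parameters <- function() {
  c("volume", "length", "surface_area", "mca", "lat", "ap",
    "mean_csa", "lat_ap_ratio", "uniformity", "sphericity")
}

#' Convert per-subject airway parameters to long cohort format
#'
#' @param params an `airway_parameters` data frame from [measure_airway()]
#'   or [analytic_truth()].
#' @param subject_id subject identifier.
#' @param timepoint `"T0"` or `"T1"`.
#' @param operator operator tag (default `"op1"`).
#' @return long data frame with columns subject_id, timepoint, operator,
#'   region, parameter, value. Surface area is the open SA (the closed SA'
#'   enters only through sphericity).
#' @export
parameters_to_long <- function(params, subject_id, timepoint, operator = "op1") {
  map <- c(volume = "V", length = "L", surface_area = "SA", mca = "MCA",
           lat = "LAT", ap = "AP", mean_csa = "meanCSA",
           lat_ap_ratio = "lat_ap_ratio", uniformity = "uniformity",
           sphericity = "sphericity")
  do.call(rbind, lapply(names(map), function(p) {
    data.frame(subject_id = subject_id, timepoint = timepoint,
               operator = operator, region = params$region,
               parameter = p, value = params[[map[[p]]]])
  }))
}

#' Cohort-level variation report
#'
#' Summarizes a paired cohort into one row per (parameter, region): T0/T1
#' descriptives, per-subject relative differences (mean/SD/min/max over
#' subjects), the ICC with its reliability class, Bland-Altman mean/SD of
#' differences with 95% limits of agreement, mean/SD of absolute
#' differences, and the smallest detectable difference. With 10 parameters
#' and 5 regions the report has 50 rows.
#'
#' Degenerate blocks (zero total variance) yield `icc = NA` with class
#' `"undefined"` instead of a silent numeric.
#'
#' @param cohort long data frame with columns subject_id, timepoint
#'   (`"T0"`/`"T1"`), region, parameter, value (see [parameters_to_long()]).
#' @param icc_model passed to [icc()].
#' @return data frame of class `variation_report`.
#' @export
summarize_cohort <- function(cohort, icc_model = "icc2_1") {
  need <- c("subject_id", "timepoint", "region", "parameter", "value")
  if (!all(need %in% names(cohort)))
    abort_data("cohort must have columns %s", paste(need, collapse = ", "))
  regions <- airway_regions()
  params <- report_parameters()
  rows <- list()
  for (p in params) for (r in regions) {
    blk <- cohort[cohort$parameter == p & cohort$region == r, ]
    w0 <- blk[blk$timepoint == "T0", ]
    w1 <- blk[blk$timepoint == "T1", ]
    subj <- sort(unique(blk$subject_id))
    v0 <- w0$value[match(subj, w0$subject_id)]
    v1 <- w1$value[match(subj, w1$subject_id)]
    if (anyNA(match(subj, w0$subject_id)) || anyNA(match(subj, w1$subject_id)))
      abort_data("subject %s is missing a timepoint for %s/%s",
                 subj[which(is.na(match(subj, w0$subject_id)) |
                            is.na(match(subj, w1$subject_id)))[1]], p, r)
    if (length(subj) == 0)
      abort_data("no measurements for parameter '%s' in region '%s'", p, r)
    rd <- relative_difference(v0, v1)
    ic <- tryCatch(icc(v0, v1, model = icc_model),
                   aw_undefined_statistic = function(e)
                     list(icc = NA_real_, icc_class = "undefined"))
    ba <- bland_altman(v0, v1)
    d <- v0 - v1
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = p, region = r, n = length(subj),
      mean_t0 = mean(v0), sd_t0 = sd(v0),
      mean_t1 = mean(v1), sd_t1 = sd(v1),
      rd_mean = mean(rd), rd_sd = sd(rd), rd_min = min(rd), rd_max = max(rd),
      icc = ic$icc, icc_class = ic$icc_class,
      diff_mean = ba$diff_mean, diff_sd = ba$diff_sd,
      abs_diff_mean = mean(abs(d)), abs_diff_sd = sd(abs(d)),
      loa_upper = ba$loa_upper, loa_lower = ba$loa_lower,
      sdd = 1.96 * ba$diff_sd)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("variation_report", "data.frame")
  out
}
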