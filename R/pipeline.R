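# End-to-end orchestration: configuration, the paired-scan pipeline
# (frame -> segmentation -> morphometry -> per-subject comparison), and the
# command-line interface.

#' Pipeline configuration
#'
#' @param air_threshold HU level separating air from soft tissue; voxels
#'   strictly below it are air (default -400).
#' @param hard_tissue_threshold HU level of the bone reconstruction; recorded
#'   as metadata only (default 300).
#' @param icc_model ICC variant for cohort reports (see [icc()]).
#' @param surface_method `"mesh"` or `"voxel_face"` (see [measure_surface()]).
#' @param seed integer seed for any stochastic step.
#' @param verbose log pipeline stages.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(air_threshold = -400, hard_tissue_threshold = 300,
                            icc_model = "icc2_1", surface_method = "mesh",
                            seed = 1L, verbose = FALSE) {
  if (!is.finite(air_threshold) || !is.finite(hard_tissue_threshold))
    abort_validation("thresholds must be finite")
  if (!(air_threshold < hard_tissue_threshold))
    abort_validation("air_threshold must lie below hard_tissue_threshold")
  structure(list(air_threshold = air_threshold,
                 hard_tissue_threshold = hard_tissue_threshold,
                 icc_model = icc_model, surface_method = surface_method,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#' @param path JSON file with any subset of the [pipeline_config()] fields.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, obj[intersect(names(obj), names(formals(pipeline_config)))])
}

required_airway_landmarks <- c("PNS", "TUV", "TEP", "BEP")

check_airway_landmarks <- function(landmarks, label) {
  missing <- setdiff(required_airway_landmarks, rownames(landmarks))
  if (length(missing))
    abort_validation("landmark set %s is missing: %s", label,
                     paste(missing, collapse = ", "))
  invisible(landmarks)
}

has_fh_fiducials <- function(landmarks) {
  all(c("PO_L", "PO_R", "OR") %in% rownames(landmarks))
}

# reorient a scan into the FH-horizontal frame if fiducials are available,
# and derive MUE
prepare_scan <- function(volume, landmarks, fill) {
  if (has_fh_fiducials(landmarks)) {
    fh <- construct_fh_plane(landmarks[c("PO_L", "PO_R", "OR"), ])
    ro <- reorient(volume, landmarks, fh, fill = fill)
    volume <- ro$volume; landmarks <- ro$landmarks
  }
  if (!"MUE" %in% rownames(landmarks)) {
    mue <- compute_mue(landmark(landmarks, "TUV"), landmark(landmarks, "TEP"))
    landmarks <- landmark_set(rbind(landmarks, MUE = mue))
  }
  list(volume = volume, landmarks = landmarks)
}

#' Run the paired-scan measurement pipeline for one subject
#'
#' Reorients the T0 scan into the Frankfort-horizontal frame, rigidly
#' superimposes the T1 scan onto T0 via the shared fiducials (falling back
#' to T1's own reorientation when fiducials are absent), reuses the bony PNS
#' landmark of T0 for T1, segments both scans (threshold, boundary crop,
#' island and dead-space removal, region partition), measures all parameters
#' and tabulates per-subject relative differences.
#'
#' @param volume_t0,volume_t1 [volume_image()]s of the two acquisitions.
#' @param landmarks_t0,landmarks_t1 [landmark_set()]s with PNS, TUV, TEP,
#'   BEP (PNS of T1 is ignored) and optionally PO_L, PO_R, OR fiducials.
#' @param config a [pipeline_config()].
#' @param subject_id identifier used in the output tables.
#' @return list with `parameters` (long data frame over both timepoints),
#'   `comparison` (per parameter x region relative differences),
#'   `t0`/`t1` (each: `mask`, `partition`, `params`).
#' @export
run_pipeline <- function(volume_t0, volume_t1, landmarks_t0, landmarks_t1,
                         config = pipeline_config(), subject_id = "S01") {
  check_airway_landmarks(landmarks_t0, "T0")
  check_airway_landmarks(landmarks_t1, "T1")
  say <- function(...) if (config$verbose) message(sprintf(...))

  say("[%s] preparing T0 frame", subject_id)
  s0 <- prepare_scan(volume_t0, landmarks_t0, fill = 40)

  if (has_fh_fiducials(landmarks_t0) && has_fh_fiducials(landmarks_t1)) {
    say("[%s] superimposing T1 on T0 via fiducials", subject_id)
    tf <- superimpose(landmarks_t1[c("PO_L", "PO_R", "OR"), ],
                      s0$landmarks[c("PO_L", "PO_R", "OR"), ])
    lm1 <- apply_transform(tf, landmarks_t1)
    fhh <- construct_fh_plane(lm1[c("PO_L", "PO_R", "OR"), ])
    ro1 <- reorient(volume_t1, lm1, fhh, fill = 40)
    # resample T1 onto an FH-horizontal grid after superimposition
    v1 <- ro1$volume; lm1 <- ro1$landmarks
    s1 <- list(volume = v1, landmarks = lm1)
    if (!"MUE" %in% rownames(s1$landmarks)) {
      mue <- compute_mue(landmark(s1$landmarks, "TUV"), landmark(s1$landmarks, "TEP"))
      s1$landmarks <- landmark_set(rbind(s1$landmarks, MUE = mue))
    }
  } else {
    s1 <- prepare_scan(volume_t1, landmarks_t1, fill = 40)
  }
  # PNS is bony: localized once on T0 and reused for T1
  s1$landmarks["PNS", ] <- s0$landmarks["PNS", ]

  say("[%s] segmenting T0", subject_id)
  seg0 <- segment_airway(s0$volume, s0$landmarks, config$air_threshold,
                         verbose = config$verbose)
  say("[%s] segmenting T1", subject_id)
  seg1 <- segment_airway(s1$volume, s1$landmarks, config$air_threshold,
                         verbose = config$verbose)

  p0 <- measure_airway(seg0$mask, seg0$partition,
                       midsagittal_x = landmark(s0$landmarks, "PNS")[1],
                       surface_method = config$surface_method)
  p1 <- measure_airway(seg1$mask, seg1$partition,
                       midsagittal_x = landmark(s1$landmarks, "PNS")[1],
                       surface_method = config$surface_method)

  long <- rbind(parameters_to_long(p0, subject_id, "T0"),
                parameters_to_long(p1, subject_id, "T1"))
  w0 <- long[long$timepoint == "T0", ]
  w1 <- long[long$timepoint == "T1", ]
  key <- paste(w0$region, w0$parameter)
  m <- match(key, paste(w1$region, w1$parameter))
  comparison <- data.frame(
    subject_id = subject_id, region = w0$region, parameter = w0$parameter,
    value_t0 = w0$value, value_t1 = w1$value[m],
    rel_diff_pct = ifelse(
      (w0$value + w1$value[m]) / 2 == 0, NA_real_,
      100 * abs(w0$value - w1$value[m]) / abs((w0$value + w1$value[m]) / 2)))
  list(parameters = long, comparison = comparison,
       t0 = list(mask = seg0$mask, partition = seg0$partition, params = p0),
       t1 = list(mask = seg1$mask, partition = seg1$partition, params = p1))
}

#' Command-line interface
#'
#' Subcommands:
#' \describe{
#'   \item{phantom}{`--out DIR --subjects N --seed S [--spacing MM --noise HU]`
#'     generate a paired phantom cohort (volumes as .nii.gz, landmarks as
#'     JSON, analytic truth as CSV).}
#'   \item{measure}{`--volume F --landmarks F --out F.csv [--subject ID
#'     --timepoint T0 --threshold -400]` measure one scan.}
#'   \item{compare}{`--volume-t0 F --volume-t1 F --landmarks-t0 F
#'     --landmarks-t1 F --out PREFIX` run the paired pipeline for one
#'     subject.}
#'   \item{report}{`--input cohort.csv --out PREFIX` cohort variation report
#'     (CSV + JSON).}
#' }
#'
#' @param args character vector of command-line arguments (default: the
#'   process arguments).
#' @return exit status 0, invisibly; called for its side effects.
#' @export
airway_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0)
    stop("usage: airwaymorph <phantom|measure|compare|report> [options]", call. = FALSE)
  cmd <- args[1]; rest <- args[-1]
  opt <- cli_parse(rest)
  switch(cmd,
    phantom = cli_phantom(opt),
    measure = cli_measure(opt),
    compare = cli_compare(opt),
    report = cli_report(opt),
    stop(sprintf("unknown subcommand '%s'", cmd), call. = FALSE))
  invisible(0L)
}

cli_parse <- function(args) {
  opt <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop(sprintf("unexpected argument '%s'", a), call. = FALSE)
    key <- gsub("-", "_", substring(a, 3))
    if (i == length(args) || startsWith(args[i + 1], "--")) {
      opt[[key]] <- TRUE; i <- i + 1L
    } else {
      opt[[key]] <- args[i + 1]; i <- i + 2L
    }
  }
  opt
}

cli_need <- function(opt, keys) {
  missing <- setdiff(keys, names(opt))
  if (length(missing))
    stop(sprintf("missing required option(s): %s",
                 paste0("--", gsub("_", "-", missing), collapse = ", ")), call. = FALSE)
}

cli_phantom <- function(opt) {
  cli_need(opt, c("out"))
  n <- as.integer(opt$subjects %||% 2L)
  seed <- as.integer(opt$seed %||% 1L)
  spacing <- as.numeric(opt$spacing %||% 0.5)
  noise <- as.numeric(opt$noise %||% 10)
  dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
  base <- default_phantom_spec(voxel_spacing = rep(spacing, 3), noise_sd = noise)
  cohort <- make_paired_cohort(n, base_spec = base, seed = seed)
  for (subj in cohort) {
    for (tp in c("t0", "t1")) {
      ph <- make_phantom(subj[[paste0("spec_", tp)]],
                         seed = seed + match(tp, c("t0", "t1")))
      stem <- file.path(opt$out, paste0(subj$subject_id, "_", toupper(tp)))
      write_volume(ph$volume, paste0(stem, ".nii.gz"))
      write_landmarks(ph$landmarks, paste0(stem, "_landmarks.json"))
      write_parameters_csv(ph$truth, paste0(stem, "_truth.csv"),
                           subject_id = subj$subject_id, timepoint = toupper(tp))
    }
    message(sprintf("wrote %s", subj$subject_id))
  }
}

cli_measure <- function(opt) {
  cli_need(opt, c("volume", "landmarks", "out"))
  vol <- read_volume(opt$volume)
  lms <- read_landmarks(opt$landmarks)
  threshold <- as.numeric(opt$threshold %||% -400)
  prep <- prepare_scan(vol, lms, fill = 40)
  seg <- segment_airway(prep$volume, prep$landmarks, threshold)
  params <- measure_airway(seg$mask, seg$partition,
                           midsagittal_x = landmark(prep$landmarks, "PNS")[1])
  write_parameters_csv(params, opt$out,
                       subject_id = opt$subject %||% "S01",
                       timepoint = opt$timepoint %||% "T0")
  message(sprintf("wrote %s", opt$out))
}

cli_compare <- function(opt) {
  cli_need(opt, c("volume_t0", "volume_t1", "landmarks_t0", "landmarks_t1", "out"))
  res <- run_pipeline(read_volume(opt$volume_t0), read_volume(opt$volume_t1),
                      read_landmarks(opt$landmarks_t0),
                      read_landmarks(opt$landmarks_t1),
                      config = pipeline_config(
                        air_threshold = as.numeric(opt$threshold %||% -400)),
                      subject_id = opt$subject %||% "S01")
  write.csv(res$parameters, paste0(opt$out, "_parameters.csv"), row.names = FALSE)
  write.csv(res$comparison, paste0(opt$out, "_comparison.csv"), row.names = FALSE)
  message(sprintf("wrote %s_{parameters,comparison}.csv", opt$out))
}

cli_report <- function(opt) {
  cli_need(opt, c("input", "out"))
  cohort <- read.csv(opt$input, stringsAsFactors = FALSE)
  report <- summarize_cohort(cohort)
  desc_cols <- c("parameter", "region", "n", "mean_t0", "sd_t0", "mean_t1",
                 "sd_t1", "rd_mean", "rd_sd", "rd_min", "rd_max", "icc",
                 "icc_class")
  ba_cols <- c("parameter", "region", "n", "diff_mean", "diff_sd",
               "abs_diff_mean", "abs_diff_sd", "loa_upper", "loa_lower", "sdd")
  write.csv(report[, desc_cols], paste0(opt$out, "_variation.csv"), row.names = FALSE)
  write.csv(report[, ba_cols], paste0(opt$out, "_agreement.csv"), row.names = FALSE)
  jsonlite::write_json(report, paste0(opt$out, "_report.json"),
                       digits = NA, dataframe = "rows")
  message(sprintf("wrote %s_{variation,agreement}.csv and %s_report.json",
                  opt$out, opt$out))
}
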