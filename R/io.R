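# File formats. No NIfTI or DICOM reader exists in the dependency
# environment, so the package carries its own minimal, self-consistent
# implementations:
#  * NIfTI-1 (.nii / .nii.gz), axis-aligned sform only, scalar datatypes;
#  * DICOM series, explicit-VR little-endian, uncompressed, axial,
#    axis-aligned (the subset a standard CT export produces and the subset
#    our synthetic writer emits).
# Landmarks travel as JSON {name: [x, y, z]} in mm; parameters and reports
# as long-format CSV.

NIFTI_DTYPES <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE, bitpix = 8L),
  `4`  = list(what = "integer", size = 2L, signed = TRUE,  bitpix = 16L),
  `8`  = list(what = "integer", size = 4L, signed = TRUE,  bitpix = 32L),
  `16` = list(what = "numeric", size = 4L, signed = TRUE,  bitpix = 32L),
  `64` = list(what = "numeric", size = 8L, signed = TRUE,  bitpix = 64L),
  `512` = list(what = "integer", size = 2L, signed = FALSE, bitpix = 16L))

#' Write a volume as NIfTI-1
#'
#' @param volume a [volume_image()] or [airway_mask()] (masks are written as
#'   uint8 0/1).
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  is_mask <- inherits(volume, "airway_mask")
  data <- volume$data
  # float64 for HU so artifact round-trips are exact to 1e-9; uint8 for masks
  datatype <- if (is_mask) 2L else 64L
  dt <- NIFTI_DTYPES[[as.character(datatype)]]
  i16 <- function(v) writeBin(as.integer(v), raw(), size = 2L, endian = "little")
  i32 <- function(v) writeBin(as.integer(v), raw(), size = 4L, endian = "little")
  f32 <- function(v) writeBin(as.numeric(v), raw(), size = 4L, endian = "little")
  d <- dim(data)
  hdr <- c(
    i32(348L),                                   # sizeof_hdr
    raw(36L),                                    # data_type..dim_info
    i16(c(3L, d, 1L, 1L, 1L, 1L)),               # dim[8]
    f32(c(0, 0, 0)), i16(0L),                    # intent_p1..p3, intent_code
    i16(datatype), i16(dt$bitpix), i16(0L),      # datatype, bitpix, slice_start
    f32(c(1, volume$spacing, 1, 1, 1, 1)),       # pixdim[8]
    f32(352), f32(1), f32(0),                    # vox_offset, scl_slope, scl_inter
    i16(0L), raw(1L), as.raw(2L),                # slice_end, slice_code, xyzt=mm
    f32(c(0, 0, 0, 0)), i32(c(0L, 0L)),          # cal/slice_duration/toffset, glmax/glmin
    raw(104L),                                   # descrip + aux_file
    i16(0L), i16(1L),                            # qform_code = 0, sform_code = 1
    f32(rep(0, 6)),                              # quatern_b..qoffset_z
    f32(c(volume$spacing[1], 0, 0, volume$origin[1])),
    f32(c(0, volume$spacing[2], 0, volume$origin[2])),
    f32(c(0, 0, volume$spacing[3], volume$origin[3])),
    raw(16L),                                    # intent_name
    charToRaw("n+1"), raw(1L),                   # magic
    raw(4L))                                     # extension flag
  stopifnot(length(hdr) == 352L)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  vals <- as.vector(data)
  if (dt$what == "integer") {
    writeBin(as.integer(vals), con, size = dt$size, endian = "little")
  } else {
    writeBin(as.numeric(vals), con, size = dt$size, endian = "little")
  }
  invisible(path)
}

#' Read a CT volume
#'
#' Accepts a NIfTI-1 file (`.nii` / `.nii.gz`) or a directory holding a
#' DICOM series. The grid is returned in the internal frame with mm spacing
#' taken from the header; files without usable spacing are rejected.
#'
#' @param path file or DICOM directory.
#' @return A [volume_image()].
#' @export
read_volume <- function(path) {
  if (dir.exists(path)) return(read_dicom_series(path))
  if (!file.exists(path)) abort_format("no such file: %s", path)
  read_nifti(path)
}

read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  rB <- function(n, what, size, signed = TRUE)
    readBin(con, what, n = n, size = size, endian = "little", signed = signed)
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) abort_format("file too short for a NIfTI header: %s", path)
  geti16 <- function(off, n = 1L) readBin(hdr[(off + 1):(off + 2 * n)], "integer",
                                          n = n, size = 2L, endian = "little")
  getf32 <- function(off, n = 1L) readBin(hdr[(off + 1):(off + 4 * n)], "numeric",
                                          n = n, size = 4L, endian = "little")
  sizeof <- readBin(hdr[1:4], "integer", size = 4L, endian = "little")
  if (sizeof != 348L) abort_format("not a little-endian NIfTI-1 file: %s", path)
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) abort_format("bad NIfTI magic '%s' in %s", magic, path)
  dim8 <- geti16(40L, 8L)
  if (dim8[1] < 3L) abort_format("volume must be 3D: %s", path)
  d <- dim8[2:4]
  datatype <- geti16(70L)
  dt <- NIFTI_DTYPES[[as.character(datatype)]]
  if (is.null(dt)) abort_format("unsupported NIfTI datatype %d in %s", datatype, path)
  pixdim <- getf32(76L, 8L)
  spacing <- pixdim[2:4]
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    abort_format("missing or invalid voxel spacing in %s", path)
  vox_offset <- getf32(108L)
  scl_slope <- getf32(112L); scl_inter <- getf32(116L)
  sform_code <- geti16(254L)
  origin <- c(0, 0, 0)
  if (sform_code > 0L) {
    srow <- rbind(getf32(280L, 4L), getf32(296L, 4L), getf32(312L, 4L))
    offdiag <- srow[, 1:3]; diag(offdiag) <- 0
    if (any(abs(offdiag) > 1e-4 * max(abs(spacing))))
      abort_format("only axis-aligned volumes are supported: %s", path)
    origin <- srow[, 4]
  }
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = as.integer(skip))
  n <- prod(d)
  vals <- rB(n, dt$what, dt$size, dt$signed)
  if (length(vals) < n) abort_format("truncated voxel data in %s", path)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  arr <- array(as.numeric(vals), d)
  volume_image(arr, spacing, origin)
}

# --- minimal DICOM series reader (explicit VR, little endian, axial) -------

dicom_parse_file <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    abort_format("not a DICOM part-10 file: %s", path)
  pos <- 133L
  u16 <- function(p) readBin(raw[p:(p + 1)], "integer", size = 2, signed = FALSE,
                             endian = "little")
  u32 <- function(p) readBin(raw[p:(p + 3)], "integer", size = 4, endian = "little")
  tags <- list()
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 7 <= length(raw)) {
    group <- u16(pos); elem <- u16(pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% long_vrs) {
      len <- u32(pos + 8L); hdr <- 12L
    } else {
      len <- u16(pos + 6L); hdr <- 8L
    }
    if (len < 0 || vr == "SQ")
      abort_format("unsupported DICOM element (undefined length or SQ) in %s", path)
    key <- sprintf("%04x%04x", group, elem)
    tags[[key]] <- list(vr = vr, start = pos + hdr, len = len)
    pos <- pos + hdr + len
    if (key == "7fe00010") break
  }
  get_str <- function(key) {
    t <- tags[[key]]
    if (is.null(t)) return(NULL)
    trimws(rawToChar(raw[t$start:(t$start + t$len - 1L)]))
  }
  get_ds <- function(key) {
    s <- get_str(key)
    if (is.null(s)) return(NULL)
    as.numeric(strsplit(s, "\\\\")[[1]])
  }
  get_us <- function(key) {
    t <- tags[[key]]
    if (is.null(t)) return(NULL)
    readBin(raw[t$start:(t$start + 1L)], "integer", size = 2, signed = FALSE,
            endian = "little")
  }
  rows <- get_us("00280010"); cols <- get_us("00280011")
  if (is.null(rows) || is.null(cols)) abort_format("missing Rows/Columns in %s", path)
  ps <- get_ds("00280030")
  if (is.null(ps)) abort_format("missing PixelSpacing in %s", path)
  bits <- get_us("00280100") %||% 16L
  if (bits != 16L) abort_format("only 16-bit DICOM pixel data supported (%s)", path)
  signed <- (get_us("00280103") %||% 1L) == 1L
  slope <- (get_ds("00281053") %||% 1)[1]
  inter <- (get_ds("00281052") %||% 0)[1]
  ipp <- get_ds("00200032") %||% c(0, 0, 0)
  thick <- (get_ds("00180050") %||% NA_real_)[1]
  pd <- tags[["7fe00010"]]
  if (is.null(pd)) abort_format("missing PixelData in %s", path)
  px <- readBin(raw[pd$start:(pd$start + pd$len - 1L)], "integer", size = 2,
                n = rows * cols, signed = signed, endian = "little")
  list(rows = rows, cols = cols, row_spacing = ps[1], col_spacing = ps[2],
       ipp = ipp, thickness = thick,
       hu = matrix(px * slope + inter, nrow = cols, ncol = rows))
}

read_dicom_series <- function(dir) {
  files <- sort(list.files(dir, full.names = TRUE))
  files <- files[!dir.exists(files)]
  if (length(files) == 0) abort_format("no files in DICOM directory %s", dir)
  slices <- lapply(files, dicom_parse_file)
  z <- vapply(slices, function(s) s$ipp[3], numeric(1))
  ord <- order(z)
  slices <- slices[ord]; z <- z[ord]
  dz <- if (length(z) > 1) {
    steps <- diff(z)
    if (any(abs(steps - steps[1]) > 1e-4))
      abort_format("non-uniform slice positions in %s", dir)
    steps[1]
  } else slices[[1]]$thickness
  if (is.null(dz) || !is.finite(dz) || dz <= 0)
    abort_format("cannot determine slice spacing in %s", dir)
  s1 <- slices[[1]]
  arr <- array(NA_real_, c(s1$cols, s1$rows, length(slices)))
  for (k in seq_along(slices)) arr[, , k] <- slices[[k]]$hu
  volume_image(arr, c(s1$col_spacing, s1$row_spacing, dz),
               c(s1$ipp[1], s1$ipp[2], z[1]))
}

#' Write a synthetic DICOM series
#'
#' Emits an uncompressed explicit-VR little-endian axial series (one file
#' per slice, int16 pixels with CT-style rescale intercept -1024). Intended
#' for tests and round-trip validation of [read_volume()]; the files carry a
#' SYNTHETIC series description and no patient data.
#'
#' @param volume a [volume_image()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dicom_series <- function(volume, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(volume$data)
  el <- function(group, elem, vr, value_raw) {
    len <- length(value_raw)
    if (len %% 2L == 1L) { value_raw <- c(value_raw, as.raw(0L)); len <- len + 1L }
    head <- c(writeBin(c(group, elem), raw(), size = 2, endian = "little"),
              charToRaw(vr))
    if (vr %in% c("OB", "OW", "OF", "UT", "UN")) {
      head <- c(head, raw(2), writeBin(as.integer(len), raw(), size = 4, endian = "little"))
    } else {
      head <- c(head, writeBin(as.integer(len), raw(), size = 2, endian = "little"))
    }
    c(head, value_raw)
  }
  str_raw <- function(s) charToRaw(s)
  us_raw <- function(v) writeBin(as.integer(v), raw(), size = 2, endian = "little")
  for (k in seq_len(d[3])) {
    z <- volume$origin[3] + (k - 1) * volume$spacing[3]
    px <- as.integer(round(volume$data[, , k] + 1024))
    meta <- c(
      el(0x0002L, 0x0010L, "UI", str_raw("1.2.840.10008.1.2.1")))
    body <- c(
      el(0x0008L, 0x0060L, "CS", str_raw("CT")),
      el(0x0008L, 0x103eL, "LO", str_raw("SYNTHETIC PHANTOM")),
      el(0x0020L, 0x0032L, "DS", str_raw(sprintf("%g\\%g\\%g", volume$origin[1],
                                                 volume$origin[2], z))),
      el(0x0018L, 0x0050L, "DS", str_raw(sprintf("%g", volume$spacing[3]))),
      el(0x0028L, 0x0010L, "US", us_raw(d[2])),      # Rows = y
      el(0x0028L, 0x0011L, "US", us_raw(d[1])),      # Columns = x
      el(0x0028L, 0x0030L, "DS", str_raw(sprintf("%g\\%g", volume$spacing[2],
                                                 volume$spacing[1]))),
      el(0x0028L, 0x0100L, "US", us_raw(16L)),
      el(0x0028L, 0x0103L, "US", us_raw(1L)),
      el(0x0028L, 0x1052L, "DS", str_raw("-1024")),
      el(0x0028L, 0x1053L, "DS", str_raw("1")),
      el(0x7fe0L, 0x0010L, "OW",
         writeBin(px, raw(), size = 2, endian = "little")))
    con <- file(file.path(dir, sprintf("slice_%04d.dcm", k)), "wb")
    writeBin(raw(128), con)
    writeChar("DICM", con, eos = NULL)
    writeBin(c(meta, body), con)
    close(con)
  }
  invisible(dir)
}

#' Read landmarks from JSON
#' @param path JSON file of the form `{"PNS": [x, y, z], ...}` (mm).
#' @return A [landmark_set()].
#' @export
read_landmarks <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.list(obj) && !is.matrix(obj)) abort_format("landmark JSON must be an object of points")
  landmark_set(obj)
}

#' Write landmarks to JSON
#' @param landmarks a [landmark_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  obj <- lapply(seq_len(nrow(landmarks)), function(i) as.numeric(landmarks[i, ]))
  names(obj) <- rownames(landmarks)
  jsonlite::write_json(obj, path, digits = NA)
  invisible(path)
}

#' Write a rigid transform as a homogeneous 4x4 matrix JSON
#' @param transform a [rigid_transform()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_transform <- function(transform, path) {
  m <- rbind(cbind(transform$rotation, transform$translation), c(0, 0, 0, 1))
  jsonlite::write_json(m, path, digits = NA)
  invisible(path)
}

#' Read a rigid transform from JSON
#' @param path JSON file holding a homogeneous 4x4 matrix.
#' @return A [rigid_transform()].
#' @export
read_transform <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- matrix(unlist(m), 4, 4, byrow = FALSE)
  if (!all(dim(m) == c(4, 4))) abort_format("transform JSON must be a 4x4 matrix")
  rigid_transform(m[1:3, 1:3], m[1:3, 4])
}

PARAMETER_UNITS <- c(volume = "mm3", length = "mm", surface_area = "mm2",
                     mca = "mm2", lat = "mm", ap = "mm", mean_csa = "mm2",
                     lat_ap_ratio = "", uniformity = "", sphericity = "")

#' Write airway parameters as long-format CSV
#'
#' Columns: subject_id, timepoint, region, parameter, value, unit.
#'
#' @param params an `airway_parameters` data frame.
#' @param path output CSV path.
#' @param subject_id,timepoint identifiers recorded in the rows.
#' @return `path`, invisibly.
#' @export
write_parameters_csv <- function(params, path, subject_id = "S01",
                                 timepoint = "T0") {
  long <- parameters_to_long(params, subject_id, timepoint)
  long$unit <- PARAMETER_UNITS[long$parameter]
  long$operator <- NULL
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Export a mesh of a mask surface as ASCII STL
#'
#' @param mask an [airway_mask()].
#' @param path output `.stl` path.
#' @param smooth_sigma mesh pre-smoothing in voxels (see [measure_surface()]).
#' @return `path`, invisibly.
#' @export
write_surface_stl <- function(mask, path, smooth_sigma = 1.0) {
  if (!any(mask$data)) abort_empty("mask is empty; no surface to export")
  pad <- as.integer(ceiling(4 * smooth_sigma)) + 1L
  d <- dim(mask$data)
  ext <- array(FALSE, d + 2L * pad)
  ext[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <- mask$data
  field <- .cpp_smooth3d(as.numeric(ext), dim(ext), smooth_sigma)
  tris <- .cpp_march_tets(field, dim(ext), 0.5, mask$spacing)
  off <- mask$origin - pad * mask$spacing
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid airway", con)
  for (r in seq_len(nrow(tris))) {
    v <- matrix(tris[r, ], 3, 3, byrow = TRUE) + matrix(off, 3, 3, byrow = TRUE)
    writeLines(c("facet normal 0 0 0", "  outer loop",
                 sprintf("    vertex %g %g %g", v[, 1], v[, 2], v[, 3]),
                 "  endloop", "endfacet"), con)
  }
  writeLines("endsolid airway", con)
  invisible(path)
}
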