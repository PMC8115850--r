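# Minimal DICOM CT series I/O: explicit-VR little-endian, one file per axial
# slice, the standard CT IOD tags needed for geometry and HU conversion
# (PixelSpacing, ImagePositionPatient, SliceThickness, RescaleSlope/Intercept,
# SeriesInstanceUID). Written files carry a standard 128-byte preamble +
# "DICM" and a group-0002 file meta header, so they are readable by common
# DICOM tooling.

DCM_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
DCM_CT_SOP_CLASS <- "1.2.840.10008.5.1.4.1.1.2"
DCM_UID_ROOT <- "1.2.826.0.1.3680043.10.424"

dcm_new_uid <- function() {
  paste0(DCM_UID_ROOT, ".", paste(sample(0:9, 20, replace = TRUE), collapse = ""))
}

dcm_uint16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
dcm_uint32 <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")

DCM_LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

# Encode one data element (explicit VR little endian).
dcm_elem <- function(group, elem, vr, value) {
  if (vr %in% c("UI", "CS", "LO", "PN", "DS", "IS", "SH")) {
    val <- charToRaw(value)
    if (length(val) %% 2L == 1L) {
      val <- c(val, if (vr == "UI") as.raw(0L) else charToRaw(" "))
    }
  } else if (vr == "US") {
    val <- dcm_uint16(value)
  } else if (vr == "UL") {
    val <- dcm_uint32(value)
  } else if (vr %in% c("OW", "OB")) {
    val <- value  # already raw
  } else {
    stop("unsupported VR: ", vr)
  }
  hdr <- c(dcm_uint16(group), dcm_uint16(elem), charToRaw(vr))
  if (vr %in% DCM_LONG_VRS) {
    c(hdr, as.raw(c(0L, 0L)), dcm_uint32(length(val)), val)
  } else {
    c(hdr, dcm_uint16(length(val)), val)
  }
}

dcm_number <- function(x) {
  paste(vapply(x, function(v) sprintf("%.8g", v), character(1)), collapse = "\\")
}

# Write one slice as a DICOM file. `pixels` is an integer matrix in (y, x)
# i.e. (row, column) order; stored values must already fit signed 16-bit.
dcm_write_slice <- function(path, pixels, position, pixel_spacing, slope,
                            intercept, series_uid, study_uid, subject_id,
                            instance, slice_thickness = NULL) {
  sop_uid <- dcm_new_uid()
  meta <- c(
    dcm_elem(0x0002, 0x0001, "OB", as.raw(c(0L, 1L))),
    dcm_elem(0x0002, 0x0002, "UI", DCM_CT_SOP_CLASS),
    dcm_elem(0x0002, 0x0003, "UI", sop_uid),
    dcm_elem(0x0002, 0x0010, "UI", DCM_EXPLICIT_LE),
    dcm_elem(0x0002, 0x0012, "UI", paste0(DCM_UID_ROOT, ".1"))
  )
  # DICOM pixel data is row-major; R matrices are column-major, so transpose.
  pix_raw <- writeBin(as.integer(t(pixels)), raw(), size = 2L, endian = "little")
  body <- c(
    dcm_elem(0x0008, 0x0016, "UI", DCM_CT_SOP_CLASS),
    dcm_elem(0x0008, 0x0018, "UI", sop_uid),
    dcm_elem(0x0008, 0x0060, "CS", "CT"),
    dcm_elem(0x0010, 0x0020, "LO", subject_id),
    if (!is.null(slice_thickness)) {
      dcm_elem(0x0018, 0x0050, "DS", dcm_number(slice_thickness))
    },
    dcm_elem(0x0020, 0x000D, "UI", study_uid),
    dcm_elem(0x0020, 0x000E, "UI", series_uid),
    dcm_elem(0x0020, 0x0013, "IS", as.character(instance)),
    dcm_elem(0x0020, 0x0032, "DS", dcm_number(position)),
    dcm_elem(0x0020, 0x0037, "DS", dcm_number(c(1, 0, 0, 0, 1, 0))),
    dcm_elem(0x0028, 0x0002, "US", 1L),
    dcm_elem(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcm_elem(0x0028, 0x0010, "US", nrow(pixels)),
    dcm_elem(0x0028, 0x0011, "US", ncol(pixels)),
    dcm_elem(0x0028, 0x0030, "DS", dcm_number(pixel_spacing)),
    dcm_elem(0x0028, 0x0100, "US", 16L),
    dcm_elem(0x0028, 0x0101, "US", 16L),
    dcm_elem(0x0028, 0x0102, "US", 15L),
    dcm_elem(0x0028, 0x0103, "US", 1L),
    dcm_elem(0x0028, 0x1052, "DS", dcm_number(intercept)),
    dcm_elem(0x0028, 0x1053, "DS", dcm_number(slope)),
    dcm_elem(0x7FE0, 0x0010, "OW", pix_raw)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(dcm_elem(0x0002, 0x0000, "UL", length(meta)), con)
  writeBin(meta, con)
  writeBin(body, con)
  invisible(path)
}

# Parse one DICOM file into a list keyed by "gggg,eeee" (hex). Only explicit
# VR little endian is supported; pixel data is decoded per the stored
# PixelRepresentation.
dcm_read_file <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  if (length(bytes) < 140L || rawToChar(bytes[129:132]) != "DICM") {
    stop("not a DICOM file: ", path)
  }
  pos <- 133L
  n <- length(bytes)
  elems <- list()
  u16 <- function(at) {
    as.integer(bytes[at]) + 256L * as.integer(bytes[at + 1L])
  }
  u32 <- function(at) {
    as.integer(bytes[at]) + 256 * as.integer(bytes[at + 1L]) +
      65536 * as.integer(bytes[at + 2L]) + 16777216 * as.integer(bytes[at + 3L])
  }
  rows <- cols <- NA_integer_
  signed <- TRUE
  while (pos + 7L <= n) {
    group <- u16(pos); elem <- u16(pos + 2L)
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr)) stop("unsupported transfer syntax (implicit VR?)")
    if (vr %in% DCM_LONG_VRS) {
      len <- u32(pos + 8L)
      val_at <- pos + 12L
    } else {
      len <- u16(pos + 6L)
      val_at <- pos + 8L
    }
    if (val_at + len - 1L > n) stop("truncated DICOM element")
    key <- sprintf("%04x,%04x", group, elem)
    vraw <- if (len > 0L) bytes[val_at:(val_at + len - 1L)] else raw(0L)
    value <- if (vr %in% c("UI", "CS", "LO", "PN", "DS", "IS", "SH")) {
      trimws(rawToChar(vraw[vraw != as.raw(0L)]))
    } else if (vr == "US") {
      readBin(vraw, "integer", n = len %/% 2L, size = 2L,
              signed = FALSE, endian = "little")
    } else if (vr == "UL") {
      readBin(vraw, "integer", n = len %/% 4L, size = 4L, endian = "little")
    } else if (key == "7fe0,0010") {
      readBin(vraw, "integer", n = len %/% 2L, size = 2L,
              signed = signed, endian = "little")
    } else {
      vraw
    }
    if (key == "0028,0010") rows <- value[1L]
    if (key == "0028,0011") cols <- value[1L]
    if (key == "0028,0103") signed <- value[1L] == 1L
    elems[[key]] <- value
    pos <- val_at + len
    if (len %% 2L == 1L) pos <- pos + 1L  # defensive; we never write odd lengths
  }
  ts <- elems[["0002,0010"]]
  if (!is.null(ts) && ts != DCM_EXPLICIT_LE) {
    stop("unsupported transfer syntax: ", ts)
  }
  if (!is.null(elems[["7fe0,0010"]])) {
    if (is.na(rows) || is.na(cols)) stop("pixel data without Rows/Columns")
    # stored row-major -> R column-major matrix (y, x)
    elems[["pixels"]] <- t(matrix(elems[["7fe0,0010"]], nrow = cols, ncol = rows))
    elems[["7fe0,0010"]] <- NULL
  }
  elems
}

dcm_ds <- function(elems, key) {
  v <- elems[[key]]
  if (is.null(v) || !nzchar(v)) return(NULL)
  as.numeric(strsplit(v, "\\\\")[[1]])
}

#' Read a DICOM CT series from a directory
#'
#' Loads every DICOM file in `directory`, checks that they belong to a single
#' series, and sorts the slices by their position along the stacking (z)
#' axis. If the slice-thickness tag is absent, it is inferred as the median
#' of consecutive inter-slice position differences — the missing-metadata
#' repair step that whole-body post-mortem CT exports often need.
#'
#' @param directory path to a directory of `.dcm` files (one axial slice per
#'   file, at least two slices).
#' @return An object of class `slice_stack`: list with `pixels` (list of
#'   integer matrices in `(y, x)` order), `positions` (n x 3 matrix, mm,
#'   DICOM `(x, y, z)` order), `pixel_spacing` (row, col, mm), `thickness`
#'   (mm), `thickness_inferred` (flag), `slope`, `intercept`, `series_uid`,
#'   `subject_id`.
#' @seealso [to_hounsfield()], [write_series()]
#' @export
read_series <- function(directory) {
  files <- sort(list.files(directory, pattern = "\\.dcm$", full.names = TRUE))
  if (length(files) < 2L) stop("no series")
  parsed <- lapply(files, dcm_read_file)

  uids <- vapply(parsed, function(e) e[["0020,000e"]] %||% "", character(1))
  if (length(unique(uids)) > 1L) stop("mixed series")

  shapes <- t(vapply(parsed, function(e) dim(e$pixels), integer(2)))
  if (nrow(unique(shapes)) > 1L) stop("heterogeneous slice shapes")
  spacings <- t(vapply(parsed, function(e) dcm_ds(e, "0028,0030"), numeric(2)))
  if (nrow(unique(round(spacings, 9))) > 1L) stop("heterogeneous pixel spacing")

  pos <- t(vapply(parsed, function(e) dcm_ds(e, "0020,0032"), numeric(3)))
  ord <- order(pos[, 3L])
  parsed <- parsed[ord]
  pos <- pos[ord, , drop = FALSE]

  dz <- diff(pos[, 3L])
  if (any(dz <= 0)) stop("degenerate geometry")
  if (max(dz) / min(dz) - 1 > 0.05) stop("non-uniform slice spacing")

  th <- vapply(parsed, function(e) {
    v <- dcm_ds(e, "0018,0050")
    if (is.null(v)) NA_real_ else v[1L]
  }, numeric(1))
  if (anyNA(th)) {
    thickness <- median(dz)
    inferred <- TRUE
  } else {
    thickness <- th[1L]
    inferred <- FALSE
  }

  slope <- dcm_ds(parsed[[1L]], "0028,1053")
  intercept <- dcm_ds(parsed[[1L]], "0028,1052")
  if (is.null(slope) || is.null(intercept)) {
    warning("rescale slope/intercept missing; assuming slope 1, intercept -1024")
    slope <- slope %||% 1
    intercept <- intercept %||% -1024
  }

  structure(
    list(
      pixels = lapply(parsed, `[[`, "pixels"),
      positions = pos,
      pixel_spacing = dcm_ds(parsed[[1L]], "0028,0030"),
      thickness = thickness,
      thickness_inferred = inferred,
      slope = slope[1L],
      intercept = intercept[1L],
      series_uid = uids[1L],
      subject_id = parsed[[1L]][["0010,0020"]] %||% "unknown"
    ),
    class = "slice_stack"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert a slice stack to a Hounsfield-unit volume
#'
#' Applies the stored-value to HU affine `HU = slope * stored + intercept`
#' element-wise and assembles the sorted slices into a `ct_volume` with
#' spacing `(slice thickness, row spacing, column spacing)`.
#'
#' @param stack a `slice_stack` from [read_series()].
#' @return A [ct_volume()] in HU, axes `(z, y, x)`.
#' @export
to_hounsfield <- function(stack) {
  stopifnot(inherits(stack, "slice_stack"))
  if (stack$slope == 0) stop("invalid rescale")
  d2 <- dim(stack$pixels[[1L]])
  nz <- length(stack$pixels)
  vals <- array(0, c(nz, d2[1L], d2[2L]))
  for (k in seq_len(nz)) {
    vals[k, , ] <- stack$slope * stack$pixels[[k]] + stack$intercept
  }
  ct_volume(
    vals,
    spacing = c(stack$thickness, stack$pixel_spacing[1L], stack$pixel_spacing[2L]),
    origin = c(stack$positions[1L, 3L], stack$positions[1L, 2L],
               stack$positions[1L, 1L]),
    subject_id = stack$subject_id
  )
}

#' Write a CT volume as a DICOM series
#'
#' Encodes a Hounsfield-unit volume back to stored pixel values via
#' `stored = round((HU - intercept) / slope)` and writes one explicit-VR
#' little-endian DICOM file per axial slice. Values outside the signed
#' 16-bit range are clipped with a warning. Reading the series back with
#' [read_series()] + [to_hounsfield()] reproduces the HU values within the
#' quantization bound `|slope| / 2` and spacing exactly.
#'
#' @param volume a [ct_volume()] in HU.
#' @param directory output directory (created if needed).
#' @param slope,intercept the stored-value affine to encode with (defaults
#'   1 and -1024, the usual CT convention).
#' @param write_thickness if `FALSE`, omit the slice-thickness tag so the
#'   reader must infer it from slice positions.
#' @return Invisibly, a data frame manifest: `file`, `instance`, `z_mm`.
#' @export
write_series <- function(volume, directory, slope = 1, intercept = -1024,
                         write_thickness = TRUE) {
  stopifnot(inherits(volume, "ct_volume"))
  if (slope == 0) stop("invalid rescale")
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)
  stored <- round((volume$values - intercept) / slope)
  if (min(stored) < -32768 || max(stored) > 32767) {
    warning("HU values outside signed 16-bit stored range; clipping")
    stored <- pmin(pmax(stored, -32768), 32767)
  }
  nz <- dim(stored)[1L]
  series_uid <- dcm_new_uid()
  study_uid <- dcm_new_uid()
  files <- character(nz)
  z <- numeric(nz)
  for (k in seq_len(nz)) {
    z[k] <- volume$origin[1L] + (k - 1L) * volume$spacing[1L]
    files[k] <- file.path(directory, sprintf("slice_%04d.dcm", k))
    dcm_write_slice(
      files[k],
      pixels = matrix(as.integer(stored[k, , ]), nrow = dim(stored)[2L]),
      position = c(volume$origin[3L], volume$origin[2L], z[k]),
      pixel_spacing = volume$spacing[2:3],
      slope = slope, intercept = intercept,
      series_uid = series_uid, study_uid = study_uid,
      subject_id = volume$subject_id, instance = k,
      slice_thickness = if (write_thickness) volume$spacing[1L]
    )
  }
  invisible(data.frame(file = files, instance = seq_len(nz), z_mm = z))
}
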