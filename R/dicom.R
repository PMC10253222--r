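# Minimal DICOM part-10 I/O (explicit VR, little endian).
#
# Covers exactly what a CT slice series needs: pixel data, image dimensions,
# pixel spacing, slice position and instance number.  Sequences with
# undefined length and non-trivial transfer syntaxes are out of scope; the
# phantom writer below only ever produces explicit-VR-little-endian files.

EXPLICIT_LE_UID <- "1.2.840.10008.1.2.1"
SECONDARY_CAPTURE_UID <- "1.2.840.10008.5.1.4.1.1.7"
UID_ROOT <- "1.2.826.0.1.3680043.8.498"  # generic example root

uint16le <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
uint32le <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

# VRs whose value length is a 4-byte field after 2 reserved bytes
LONG_VRS <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")

dcm_element <- function(group, elem, vr, value_raw) {
  if (length(value_raw) %% 2L == 1L) {
    pad <- if (vr %in% c("UI", "OB")) as.raw(0L) else charToRaw(" ")
    value_raw <- c(value_raw, pad)
  }
  hdr <- c(uint16le(group), uint16le(elem), charToRaw(vr))
  if (vr %in% LONG_VRS) {
    c(hdr, as.raw(c(0L, 0L)), uint32le(length(value_raw)), value_raw)
  } else {
    if (length(value_raw) > 65534) stop("value too long for short VR")
    c(hdr, uint16le(length(value_raw)), value_raw)
  }
}

dcm_str <- function(group, elem, vr, s) {
  dcm_element(group, elem, vr, charToRaw(as.character(s)))
}

dcm_us <- function(group, elem, x) dcm_element(group, elem, "US", uint16le(x))

# Deterministic instance UID derived from identifying fields.
dcm_uid <- function(...) {
  key <- paste(..., sep = "|")
  h <- sum(utf8ToInt(key) * (seq_along(utf8ToInt(key)) %% 97 + 1))
  paste(UID_ROOT, h %% 1000000L, nchar(key), sep = ".")
}

#' Write one CT slice as a minimal DICOM file
#'
#' Explicit-VR little-endian part-10 file carrying the pixel array (unsigned
#' 16-bit stored values), image dimensions, pixel spacing, slice position and
#' instance number -- the tags [load_series()] consumes.
#'
#' @param path output file path.
#' @param pixels integer matrix `pixels[x + 1, y + 1]` of non-negative stored
#'   values (< 65536).
#' @param z_mm physical slice position along the patient z axis, mm.
#' @param pixel_spacing_mm in-plane pixel spacing, mm.
#' @param instance_number 1-based slice number within the series.
#' @param case_id patient/series identifier.
#' @return `path`, invisibly.
#' @export
write_dicom <- function(path, pixels, z_mm, pixel_spacing_mm = 500 / 512,
                        instance_number = 1L, case_id = "case") {
  stopifnot(is.matrix(pixels), all(pixels >= 0), all(pixels < 65536))
  sop_uid <- dcm_uid(case_id, instance_number, "sop")
  spacing <- as.character(pixel_spacing_mm)
  meta <- c(
    dcm_element(0x0002, 0x0001, "OB", as.raw(c(0L, 1L))),
    dcm_str(0x0002, 0x0002, "UI", SECONDARY_CAPTURE_UID),
    dcm_str(0x0002, 0x0003, "UI", sop_uid),
    dcm_str(0x0002, 0x0010, "UI", EXPLICIT_LE_UID),
    dcm_str(0x0002, 0x0012, "UI", paste0(UID_ROOT, ".1"))
  )
  meta <- c(dcm_element(0x0002, 0x0000, "UL", uint32le(length(meta))), meta)
  # column-major [x, y] storage enumerates x fastest, i.e. row by row --
  # exactly the DICOM pixel stream order
  pixel_raw <- writeBin(as.integer(pixels), raw(), size = 2, endian = "little")
  body <- c(
    dcm_str(0x0008, 0x0016, "UI", SECONDARY_CAPTURE_UID),
    dcm_str(0x0008, 0x0018, "UI", sop_uid),
    dcm_str(0x0008, 0x0060, "CS", "CT"),
    dcm_str(0x0010, 0x0010, "PN", case_id),
    dcm_str(0x0010, 0x0020, "LO", case_id),
    dcm_str(0x0020, 0x000D, "UI", dcm_uid(case_id, "study")),
    dcm_str(0x0020, 0x000E, "UI", dcm_uid(case_id, "series")),
    dcm_str(0x0020, 0x0013, "IS", instance_number),
    dcm_str(0x0020, 0x0032, "DS", paste(0, 0, as.character(z_mm), sep = "\\")),
    dcm_str(0x0020, 0x1041, "DS", as.character(z_mm)),
    dcm_us(0x0028, 0x0002, 1L),
    dcm_str(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcm_us(0x0028, 0x0010, ncol(pixels)),  # Rows = H
    dcm_us(0x0028, 0x0011, nrow(pixels)),  # Columns = W
    dcm_str(0x0028, 0x0030, "DS", paste(spacing, spacing, sep = "\\")),
    dcm_us(0x0028, 0x0100, 16L),
    dcm_us(0x0028, 0x0101, 16L),
    dcm_us(0x0028, 0x0102, 15L),
    dcm_us(0x0028, 0x0103, 0L),
    dcm_element(0x7FE0, 0x0010, "OW", pixel_raw)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
  invisible(path)
}

rd_uint <- function(bytes, size) {
  n <- length(bytes) / size
  readBin(bytes, "integer", n = n, size = size, endian = "little",
          signed = size > 2)
}

#' Read a DICOM slice file
#'
#' Parses an explicit-VR little-endian part-10 file and returns the pixel
#' array plus the geometry tags needed to order and scale a slice series.
#'
#' @param path DICOM file path.
#' @return A list with `pixels` (`W x H` integer matrix, `[x + 1, y + 1]`),
#'   `pixel_spacing` (length-2 numeric, mm), `slice_position_mm`,
#'   `instance_number`, and `rows`/`cols`.
#' @export
read_dicom <- function(path) {
  bytes <- readBin(path, "raw", file.size(path))
  if (length(bytes) < 140 || rawToChar(bytes[129:132]) != "DICM") {
    stop("format error: not a DICOM part-10 file: ", path)
  }
  pos <- 133L
  tags <- list()
  while (pos + 7L <= length(bytes)) {
    group <- rd_uint(bytes[pos:(pos + 1L)], 2)
    elem <- rd_uint(bytes[(pos + 2L):(pos + 3L)], 2)
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr)) {
      stop("format error: implicit VR or corrupt element in ", path)
    }
    if (vr %in% LONG_VRS) {
      len <- rd_uint(bytes[(pos + 8L):(pos + 11L)], 4)
      pos <- pos + 12L
    } else {
      len <- rd_uint(bytes[(pos + 6L):(pos + 7L)], 2)
      pos <- pos + 8L
    }
    if (len < 0 || pos + len - 1L > length(bytes)) {
      stop("format error: element length out of bounds in ", path)
    }
    value <- if (len > 0) bytes[pos:(pos + len - 1L)] else raw(0)
    pos <- pos + len
    tags[[sprintf("%04X,%04X", group, elem)]] <- value
  }
  get_str <- function(key) {
    v <- tags[[key]]
    if (is.null(v)) return(NA_character_)
    trimws(rawToChar(v[v != as.raw(0)]))
  }
  get_us <- function(key) {
    v <- tags[[key]]
    if (is.null(v)) return(NA_integer_)
    rd_uint(v, 2)[1]
  }
  rows <- get_us("0028,0010")
  cols <- get_us("0028,0011")
  if (is.na(rows) || is.na(cols)) stop("format error: missing Rows/Columns")
  spacing <- suppressWarnings(
    as.numeric(strsplit(get_str("0028,0030"), "\\", fixed = TRUE)[[1]])
  )
  if (!length(spacing)) spacing <- NA_real_
  ipp <- suppressWarnings(
    as.numeric(strsplit(get_str("0020,0032"), "\\", fixed = TRUE)[[1]])
  )
  zpos <- if (length(ipp) >= 3) ipp[3] else
    suppressWarnings(as.numeric(get_str("0020,1041")))
  inst <- suppressWarnings(as.integer(get_str("0020,0013")))
  pix <- tags[["7FE0,0010"]]
  if (is.null(pix)) stop("format error: missing PixelData")
  vals <- rd_uint(pix[seq_len(2L * rows * cols)], 2)
  list(pixels = matrix(vals, nrow = cols, ncol = rows),
       pixel_spacing = spacing,
       slice_position_mm = zpos,
       instance_number = inst,
       rows = rows, cols = cols)
}

#' Write a case volume as a DICOM slice series
#'
#' One file per slice, named so that file order intentionally differs from
#' anatomical order is *not* required -- [load_series()] sorts by the slice
#' position tag.
#'
#' @param volume a [case_volume()].
#' @param directory output directory (created if needed).
#' @return `directory`, invisibly.
#' @export
write_series <- function(volume, directory) {
  stopifnot(inherits(volume, "case_volume"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  n <- n_slices(volume)
  for (i in seq_len(n)) {
    write_dicom(file.path(directory, sprintf("slice_%03d.dcm", i)),
                volume$pixels[, , i],
                z_mm = volume$slice_positions_mm[i],
                pixel_spacing_mm = volume$in_plane_mm,
                instance_number = i,
                case_id = volume$case_id)
  }
  invisible(directory)
}
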