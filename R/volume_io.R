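#' Case volume: an ordered caudal-to-cranial stack of raw CT slices
#'
#' @param pixels integer array `W x H x n_slices` of non-negative stored
#'   values; slice 1 is the most caudal.
#' @param case_id character scalar.
#' @param slice_positions_mm numeric vector of physical slice positions (mm),
#'   strictly increasing cranially.
#' @param in_plane_mm,slice_mm physical spacing, mm.
#' @return An object of class `case_volume`.
#' @export
case_volume <- function(pixels, case_id, slice_positions_mm,
                        in_plane_mm = 500 / 512, slice_mm = 5) {
  if (length(dim(pixels)) != 3L) stop("pixels must be a W x H x n_slices array")
  if (dim(pixels)[1] != dim(pixels)[2]) stop("slices must be square")
  if (any(pixels < 0)) stop("stored values must be non-negative")
  n <- dim(pixels)[3]
  if (length(slice_positions_mm) != n) {
    stop("slice_positions_mm must have one entry per slice")
  }
  if (n > 1 && any(diff(slice_positions_mm) <= 0)) {
    stop("slice positions must be strictly increasing (caudal first)")
  }
  structure(
    list(case_id = as.character(case_id),
         pixels = pixels,
         slice_positions_mm = as.numeric(slice_positions_mm),
         in_plane_mm = in_plane_mm,
         slice_mm = slice_mm),
    class = "case_volume"
  )
}

#' @export
print.case_volume <- function(x, ...) {
  d <- dim(x$pixels)
  cat("case_volume ", x$case_id, ": ", d[1], " x ", d[2], " px, ",
      d[3], " slices (caudal first), ",
      signif(x$in_plane_mm, 7), " mm/px, ", x$slice_mm, " mm interval\n",
      sep = "")
  invisible(x)
}

n_slices <- function(volume) dim(volume$pixels)[3]

#' Binary voxel stack
#'
#' A fixed-shape array with values in \{0, 1\}, the input fed to the
#' regression networks.  `window` records the crop placement that ties local
#' to global coordinates (`NULL` for a whole-volume stack); `scale` is the
#' in-plane compression factor relative to the original frame (1 for crops).
#'
#' @param voxels integer array `W x H x D` with values in \{0, 1\}.
#' @param window a [crop_window()] or `NULL` for a whole-volume stack.
#' @param scale in-plane compression factor.
#' @return An object of class `binary_stack`.
#' @export
binary_stack <- function(voxels, window = NULL, scale = 1) {
  if (length(dim(voxels)) != 3L) stop("voxels must be a 3D array")
  if (!all(voxels %in% c(0L, 1L))) stop("voxels must be 0/1")
  structure(list(voxels = voxels, window = window, scale = scale),
            class = "binary_stack")
}

#' @export
print.binary_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat("binary_stack ", d[1], " x ", d[2], " x ", d[3], ", ",
      sum(x$voxels), " bone voxels",
      if (!is.null(x$window)) paste0(", window origin (", x$window$x0, ", ",
                                     x$window$y0, ")"),
      "\n", sep = "")
  invisible(x)
}

#' Load a DICOM slice series as a case volume
#'
#' Reads every DICOM file in `directory`, checks that dimensions and pixel
#' spacing agree, and sorts slices by physical position so that index 0 is
#' the most caudal slice regardless of file naming (ties broken by instance
#' number).
#'
#' @param directory path containing one DICOM file per slice.
#' @param case_id identifier for the volume; defaults to the directory name.
#' @return A [case_volume()].
#' @export
load_series <- function(directory, case_id = basename(directory)) {
  files <- list.files(directory, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) stop("input error: no files in ", directory)
  slices <- lapply(files, read_dicom)
  dims <- vapply(slices, function(s) dim(s$pixels), integer(2))
  if (any(dims != dims[1, 1])) {
    stop("format error: inconsistent slice dimensions in ", directory)
  }
  spac <- vapply(slices, function(s) s$pixel_spacing[1], numeric(1))
  if (any(is.na(spac))) stop("format error: missing pixel-spacing tag")
  if (diff(range(spac)) > 1e-9) {
    stop("format error: inconsistent pixel spacing in ", directory)
  }
  z <- vapply(slices, function(s) s$slice_position_mm, numeric(1))
  if (any(is.na(z))) stop("format error: missing slice-position tag")
  inst <- vapply(slices, function(s) s$instance_number %||% NA_integer_,
                 integer(1))
  ord <- order(z, inst)
  slices <- slices[ord]
  z <- z[ord]
  px <- vapply(slices, function(s) s$pixels, slices[[1]]$pixels)
  slice_mm <- if (length(z) > 1) stats::median(diff(z)) else 5
  case_volume(px, case_id, z, in_plane_mm = spac[1], slice_mm = slice_mm)
}

#' Add the calibration cross to the most caudal slice
#'
#' Marks the fiducial used to standardize coordinate origins: on the most
#' caudal slice only, every pixel of row `cross_index` and column
#' `cross_index` (0-based) is set to `value`, a stored value far above the
#' bone threshold.  On a previously unmarked S x S slice this modifies
#' exactly `2 * S - 1` pixels.
#'
#' @param volume a [case_volume()].
#' @param cross_index 0-based row/column of the cross arms.
#' @param value stored value written on the cross.
#' @return The modified `case_volume`.
#' @export
add_calibration_cross <- function(volume, cross_index = 255L, value = 4000L) {
  stopifnot(inherits(volume, "case_volume"))
  d <- dim(volume$pixels)
  if (d[1] <= cross_index || d[2] <= cross_index) {
    stop("index error: slice smaller than the calibration-cross index")
  }
  volume$pixels[cross_index + 1L, , 1L] <- value
  volume$pixels[, cross_index + 1L, 1L] <- value
  volume
}

#' Binarize stored CT values at a bone threshold
#'
#' A cell maps to 1 iff its stored value is `>= threshold` (so the threshold
#' value itself counts as bone).  Idempotent: re-binarizing the output with
#' threshold 1 reproduces it.
#'
#' @param image numeric matrix or array of stored values.
#' @param threshold stored-value bone threshold.
#' @return An integer \{0, 1\} matrix/array of the same shape.
#' @export
binarize <- function(image, threshold = 1100L) {
  out <- (image >= threshold)
  storage.mode(out) <- "integer"
  out
}

# cache of area-resampling weight matrices, keyed by "src->tgt"
.compress_cache <- new.env(parent = emptyenv())

area_weights <- function(n_src, n_tgt) {
  key <- paste0(n_src, "->", n_tgt)
  w <- .compress_cache[[key]]
  if (!is.null(w)) return(w)
  r <- n_src / n_tgt
  w <- matrix(0, n_tgt, n_src)
  for (i in seq_len(n_tgt)) {
    lo <- (i - 1) * r
    hi <- i * r
    j0 <- floor(lo)
    j1 <- ceiling(hi) - 1
    for (j in j0:j1) {
      ov <- min(hi, j + 1) - max(lo, j)
      if (ov > 0) w[i, j + 1] <- ov / r
    }
  }
  .compress_cache[[key]] <- w
  w
}

#' Compress a square slice by area resampling
#'
#' Box (area-average) resampling on raw intensities: output cell (i, j)
#' averages the source region it covers, so constant images stay constant
#' and a source row at index `k` maps to output row `k * target / source`.
#'
#' @param image square numeric matrix.
#' @param target_size output width/height, px.
#' @return A `target_size x target_size` numeric matrix.
#' @export
compress_slice <- function(image, target_size = 96L) {
  if (target_size <= 0) stop("parameter error: target_size must be positive")
  d <- dim(image)
  if (d[1] != d[2]) stop("compress_slice requires a square input")
  if (d[1] == target_size) return(image + 0)
  w <- area_weights(d[1], target_size)
  w %*% image %*% t(w)
}

#' Build the phase-1 whole-volume input stack
#'
#' Starts from a zero template of shape `width x width x depth`; slice *i*
#' (caudal-first) is compressed to `width` px, binarized at `threshold` and
#' placed at depth index *i*, so depth layers at and beyond the slice count
#' stay zero.
#'
#' @param volume a [case_volume()].
#' @param width in-plane size of the compressed input, px.
#' @param depth number of depth layers of the template.
#' @param threshold stored-value bone threshold.
#' @return A [binary_stack()] with `scale = width / frame`.
#' @export
build_phase1_stack <- function(volume, width = 96L, depth = 81L,
                               threshold = 1100L) {
  stopifnot(inherits(volume, "case_volume"))
  n <- n_slices(volume)
  if (n > depth) {
    stop("capacity error: ", n, " slices exceed template depth ", depth)
  }
  vox <- array(0L, c(width, width, depth))
  for (i in seq_len(n)) {
    vox[, , i] <- binarize(compress_slice(volume$pixels[, , i], width),
                           threshold)
  }
  binary_stack(vox, window = NULL, scale = width / dim(volume$pixels)[1])
}
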