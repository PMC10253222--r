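#' Unit conversions between pixels, millimetres and slice indices
#'
#' The standard CT frame maps 512 px to 500 mm, i.e. 1 px = 0.9765625 mm
#' (the DICOM pixel-spacing tag of the source collections).  All coordinates,
#' including z, are kept in this pixel unit; a slice interval of 5 mm then
#' corresponds to a z step of 5.12 px, so `slice_to_zpx()` places slice *i*
#' (0-based, caudal-first) at `i * slice_mm / in_plane_mm` px.
#'
#' @param value numeric vector of pixel (or millimetre) values.
#' @param index numeric vector of 0-based slice indices.
#' @param in_plane_mm physical size of one in-plane pixel, mm.
#' @param slice_mm physical slice interval, mm.
#' @return Numeric vector of converted values.
#' @export
#' @examples
#' px_to_mm(1)    # 0.9765625
#' px_to_mm(512)  # 500
#' slice_to_zpx(10)  # 51.2
px_to_mm <- function(value, in_plane_mm = 500 / 512) {
  value * in_plane_mm
}

#' @rdname px_to_mm
#' @export
mm_to_px <- function(value, in_plane_mm = 500 / 512) {
  value / in_plane_mm
}

#' @rdname px_to_mm
#' @export
slice_to_zpx <- function(index, in_plane_mm = 500 / 512, slice_mm = 5) {
  index * slice_mm / in_plane_mm
}
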