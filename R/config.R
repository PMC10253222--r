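#' Pipeline configuration
#'
#' Bundles every geometric and training constant of the three-phase system.
#' Two standard scales ship with the package:
#'
#' * `"full"` — the standard CT scale: 512 x 512 slices, up to 81 slices at 5 mm
#'   intervals, phase-1 input compressed to 96 x 96, refinement crop widths
#'   100 and 50 px, shift grids (+-30 step 10) and (+-15 step 5).
#' * `"desk"` — a reduced scale for CPU-sized experiments on synthetic
#'   phantoms: 96 x 96 x 24 volumes, phase-1 input 18 x 18, crop widths 18
#'   and 10 px, shift grids (+-6 step 3) and (+-2 step 1), and narrow
#'   networks (`width_scale = 0.0625`).
#'
#' @param scale `"full"` (standard CT geometry) or `"desk"`.
#' @param ... named overrides of individual fields.
#' @return A list of class `craniomark_config`.
#' @export
#' @examples
#' cfg <- craniomark_config("desk", epochs = c(phase1 = 5, phase2 = 5,
#'                                             phase3 = 5))
#' cfg$threshold
craniomark_config <- function(scale = c("full", "desk"), ...) {
  scale <- match.arg(scale)
  cfg <- list(
    scale        = scale,
    frame        = 512L,    # in-plane frame width/height, px
    depth        = 81L,     # depth of the zero template (max slice count)
    phase1_size  = 96L,     # in-plane size of the compressed phase-1 input
    threshold    = 1100L,   # stored-value bone threshold
    cross_value  = 4000L,   # calibration-cross stored value
    cross_index  = 255L,    # 0-based row/column index of the cross
    apply_cross  = TRUE,    # keep the cross in network inputs
    in_plane_mm  = 500 / 512,
    slice_mm     = 5,
    crop_width   = c(phase2 = 100L, phase3 = 50L),
    max_shift    = c(phase2 = 30L, phase3 = 15L),
    shift_step   = c(phase2 = 10L, phase3 = 5L),
    width_scale  = 1,
    batch_size   = c(phase1 = 8L, phase2 = 16L, phase3 = 16L),
    epochs       = c(phase1 = 150L, phase2 = 100L, phase3 = 150L),
    lr           = 1e-3,
    seed         = 0L
  )
  if (scale == "desk") {
    # desk lengths follow the full-scale geometry scaled by the frame
    # ratio 96/512 = 0.1875 (rounded to even crop widths)
    cfg$frame       <- 96L
    cfg$depth       <- 24L
    cfg$phase1_size <- 18L
    cfg$cross_index <- 47L   # cross arms scaled to the 96-px frame
    cfg$in_plane_mm <- 500 / 96
    cfg$slice_mm    <- 4 * 500 / 96       # slice step of 4 px in z
    cfg$crop_width  <- c(phase2 = 18L, phase3 = 10L)
    # the phase-3 lattice stays within the crop half-width minus the
    # marker radius, mirroring how the full-scale shift range tracks the
    # previous phase's error scale
    cfg$max_shift   <- c(phase2 = 6L, phase3 = 2L)
    cfg$shift_step  <- c(phase2 = 3L, phase3 = 1L)
    cfg$width_scale <- 0.0625
    cfg$epochs      <- c(phase1 = 15L, phase2 = 6L, phase3 = 10L)
    cfg$lr          <- 3e-3
  }
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  structure(cfg, class = "craniomark_config")
}

#' Read a configuration from a YAML file
#'
#' The file may set `scale` plus any field of [craniomark_config()].
#'
#' @param path path to a YAML file.
#' @return A `craniomark_config`.
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading YAML configuration requires the 'yaml' package")
  }
  vals <- yaml::read_yaml(path)
  scale <- vals$scale %||% "full"
  vals$scale <- NULL
  do.call(craniomark_config, c(list(scale = scale), vals))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.craniomark_config <- function(x, ...) {
  cat("craniomark configuration (", x$scale, " scale)\n", sep = "")
  cat("  frame ", x$frame, " px, depth ", x$depth, " slices, phase-1 input ",
      x$phase1_size, " px\n", sep = "")
  cat("  bone threshold ", x$threshold, ", crop widths ",
      paste(x$crop_width, collapse = "/"), " px\n", sep = "")
  invisible(x)
}
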