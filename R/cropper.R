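#' Crop window: integer placement of a refinement crop in the global frame
#'
#' Records the global (x0, y0) of the crop's corner so that
#' `global = origin + local` holds exactly for x and y; crops always span the
#' full z extent.
#'
#' @param x0,y0 integer global px of the window corner (may be negative or
#'   beyond the frame; out-of-frame regions are zero-filled when cropping).
#' @param width crop width in px.
#' @return An object of class `crop_window`.
#' @export
crop_window <- function(x0, y0, width) {
  if (width <= 0) stop("parameter error: width must be positive")
  structure(list(x0 = as.integer(x0), y0 = as.integer(y0),
                 width = as.integer(width)),
            class = "crop_window")
}

#' Shift grid for crop augmentation
#'
#' The lattice of (dx, dy) offsets at which training crops are re-cut around
#' the true landmark.  Offsets run over the half-open range
#' `[-max_shift, +max_shift)` stepped by `step` in both axes (Cartesian
#' product), giving `(2 * max_shift / step)^2` offsets -- e.g. 36 for
#' (+-30, step 10) and for (+-15, step 5), so 90 cases yield 3240 examples.
#'
#' @param max_shift largest shift magnitude, px.
#' @param step lattice step, px; must divide `max_shift`.
#' @return An object of class `shift_grid` with an `offsets` matrix
#'   (n x 2, columns `dx`, `dy`).
#' @export
#' @examples
#' nrow(make_shift_grid(30, 10)$offsets)  # 36
make_shift_grid <- function(max_shift, step) {
  if (step <= 0) stop("parameter error: step must be positive")
  if (max_shift %% step != 0) {
    stop("parameter error: max_shift must be divisible by step")
  }
  v <- seq(-max_shift, max_shift - step, by = step)
  offs <- as.matrix(expand.grid(dx = v, dy = v))
  structure(list(max_shift = max_shift, step = step, offsets = offs),
            class = "shift_grid")
}

#' Cut a full-depth binarized crop around a point
#'
#' The window origin is `round(center) - width / 2`; each slice is binarized
#' at full resolution (no compression) and the `width x width` region is
#' copied into the stack caudal-first, zero-padding both regions outside the
#' in-plane frame and depth layers beyond the slice count.
#'
#' @param volume a [case_volume()].
#' @param center numeric (x, y) global px; may lie near or beyond borders.
#' @param width even crop width, px.
#' @param depth number of depth layers of the stack.
#' @param threshold stored-value bone threshold.
#' @return A list with `stack` (a [binary_stack()]) and `window`
#'   (the [crop_window()] used).
#' @export
crop_stack <- function(volume, center, width, depth = 81L, threshold = 1100L) {
  stopifnot(inherits(volume, "case_volume"))
  if (width %% 2L != 0L) stop("parameter error: width must be even")
  if (any(!is.finite(center[1:2]))) stop("center must be finite")
  x0 <- as.integer(round(center[1])) - width %/% 2L
  y0 <- as.integer(round(center[2])) - width %/% 2L
  d <- dim(volume$pixels)
  n <- min(n_slices(volume), depth)
  vox <- array(0L, c(width, width, depth))
  # overlap of the window [x0, x0 + width) with the frame [0, W)
  x_lo <- max(x0, 0L); x_hi <- min(x0 + width - 1L, d[1] - 1L)
  y_lo <- max(y0, 0L); y_hi <- min(y0 + width - 1L, d[2] - 1L)
  if (x_lo <= x_hi && y_lo <= y_hi) {
    gx <- x_lo:x_hi
    gy <- y_lo:y_hi
    for (i in seq_len(n)) {
      vox[gx - x0 + 1L, gy - y0 + 1L, i] <-
        binarize(volume$pixels[gx + 1L, gy + 1L, i], threshold)
    }
  }
  win <- crop_window(x0, y0, width)
  list(stack = binary_stack(vox, window = win, scale = 1), window = win)
}

#' Local training target for a crop window
#'
#' Subtracts the window origin from x and y and passes z through unchanged
#' (z stays global): the unshifted target of a width-100 crop is (50, 50, z)
#' and of a width-50 crop (25, 25, z); a crop shifted by (dx, dy) yields
#' (width/2 - dx, width/2 - dy, z).
#'
#' @param landmark numeric (x, y, z) global px.
#' @param window a [crop_window()].
#' @return Numeric (x_local, y_local, z_global).
#' @export
local_target <- function(landmark, window) {
  unname(c(landmark[1] - window$x0, landmark[2] - window$y0, landmark[3]))
}

#' Remap a local prediction to the global frame
#'
#' Adds the recorded window origin back to x and y; exact inverse of
#' [local_target()].
#'
#' @param local_pred numeric (x_local, y_local, z_global).
#' @param window a [crop_window()].
#' @return Numeric (x, y, z) global px.
#' @export
remap_to_global <- function(local_pred, window) {
  unname(c(window$x0 + local_pred[1], window$y0 + local_pred[2],
           local_pred[3]))
}

#' Build the shift-augmented refinement dataset for one landmark
#'
#' For every case and every grid offset (dx, dy), cuts a crop centred on
#' `(x + dx, y + dy)` of the true landmark and records the target
#' `local_target(landmark, window)`, i.e. `(width/2 - dx, width/2 - dy, z)`.
#' The example count is `n_cases * nrow(grid$offsets)` -- 3240 for 90 cases
#' with either of the standard grids.
#'
#' @param cases list of [case_volume()]s.
#' @param tables list of matching [landmark_table()]s (same order).
#' @param landmark_code one of `L01..L16`.
#' @param width crop width, px.
#' @param grid a [make_shift_grid()] result.
#' @param depth stack depth.
#' @param threshold stored-value bone threshold.
#' @return An object of class `refinement_dataset`: a list with `examples`
#'   (each having `stack`, `target`, `window`, `case_id`, `landmark`),
#'   `landmark`, and `width`.
#' @export
build_refinement_dataset <- function(cases, tables, landmark_code, width,
                                     grid, depth = 81L, threshold = 1100L) {
  stopifnot(inherits(grid, "shift_grid"), length(cases) == length(tables))
  if (!landmark_code %in% landmark_catalog()$code) {
    stop("input error: unknown landmark code ", landmark_code)
  }
  offs <- grid$offsets
  examples <- vector("list", length(cases) * nrow(offs))
  k <- 0L
  for (ci in seq_along(cases)) {
    lm <- tables[[ci]][landmark_code, ]
    if (any(!is.finite(lm))) {
      stop("input error: case ", case_id_of(tables[[ci]]),
           " is missing landmark ", landmark_code)
    }
    for (oi in seq_len(nrow(offs))) {
      cr <- crop_stack(cases[[ci]], c(lm[1] + offs[oi, 1], lm[2] + offs[oi, 2]),
                       width, depth, threshold)
      k <- k + 1L
      examples[[k]] <- list(stack = cr$stack,
                            target = local_target(lm, cr$window),
                            window = cr$window,
                            case_id = case_id_of(tables[[ci]]),
                            landmark = landmark_code)
    }
  }
  structure(list(examples = examples, landmark = landmark_code, width = width),
            class = "refinement_dataset")
}

#' @export
print.refinement_dataset <- function(x, ...) {
  cat("refinement_dataset: ", length(x$examples), " examples for ",
      x$landmark, ", crop width ", x$width, " px\n", sep = "")
  invisible(x)
}

#' Serialize / load a refinement dataset
#'
#' Array-container persistence of the (stack, target, window, case_id,
#' landmark) records via R's native serialization.
#'
#' @param dataset a `refinement_dataset`.
#' @param path file path.
#' @return `read_dataset()`: the restored `refinement_dataset`.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "refinement_dataset"))
  saveRDS(dataset, path)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "refinement_dataset")) {
    stop("format error: not a refinement dataset: ", path)
  }
  x
}
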