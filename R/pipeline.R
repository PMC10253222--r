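# Three-phase inference, error evaluation and phase-comparison statistics.

prepare_volume <- function(volume, config) {
  if (isTRUE(config$apply_cross) &&
      dim(volume$pixels)[1] > config$cross_index) {
    volume <- add_calibration_cross(volume, config$cross_index,
                                    config$cross_value)
  }
  volume
}

#' Build the phase-1 training dataset
#'
#' One example per case: the compressed whole-volume binary stack and the
#' 48-vector of global landmark coordinates `(x1, y1, z1, x2, ...)` in
#' catalog order.
#'
#' @param volumes list of [case_volume()]s.
#' @param tables matching list of [landmark_table()]s.
#' @param config a [craniomark_config()].
#' @return A list of examples suitable for [train_regressor()].
#' @export
build_phase1_dataset <- function(volumes, tables, config = craniomark_config()) {
  stopifnot(length(volumes) == length(tables))
  lapply(seq_along(volumes), function(i) {
    v <- prepare_volume(volumes[[i]], config)
    list(stack = build_phase1_stack(v, config$phase1_size, config$depth,
                                    config$threshold),
         target = as.numeric(t(unclass(tables[[i]]))),
         case_id = case_id_of(tables[[i]]))
  })
}

#' Phase-1 whole-volume prediction
#'
#' Feeds the compressed binary stack to the 48-output model and reshapes the
#' result to 16 points in catalog order (point *i* takes components
#' `3i-2 .. 3i` of the output).
#'
#' @param model a 48-output `craniomark_model` (or stub function).
#' @param volume a [case_volume()].
#' @param config a [craniomark_config()].
#' @return 16 x 3 matrix of global (x, y, z) px, rownames `L01..L16`.
#' @export
predict_phase1 <- function(model, volume, config = craniomark_config()) {
  v <- prepare_volume(volume, config)
  stack <- build_phase1_stack(v, config$phase1_size, config$depth,
                              config$threshold)
  out <- as.numeric(predict_coords(model, stack))
  if (length(out) != 48L) {
    stop("input error: phase-1 model must produce 48 outputs, got ",
         length(out))
  }
  m <- matrix(out, 16L, 3L, byrow = TRUE)
  dimnames(m) <- list(landmark_catalog()$code, c("x", "y", "z"))
  m
}

#' One refinement step
#'
#' Crops a full-depth window centred on the prior (x, y), predicts the local
#' coordinates with the per-landmark model, and remaps x and y to the global
#' frame through the recorded window origin; the predicted z is already
#' global and passes through.
#'
#' @param volume a [case_volume()].
#' @param prior numeric (x, y, z) global px from the previous phase.
#' @param width crop width for this phase.
#' @param model a 3-output `craniomark_model` (or stub function).
#' @param config a [craniomark_config()].
#' @return A list with `coords` (global (x, y, z)) and `window`.
#' @export
refine <- function(volume, prior, width, model, config = craniomark_config()) {
  cr <- crop_stack(volume, prior[1:2], width, config$depth, config$threshold)
  local <- as.numeric(predict_coords(model, cr$stack))
  if (length(local) != 3L) {
    stop("input error: refinement model must produce 3 outputs")
  }
  list(coords = remap_to_global(local, cr$window), window = cr$window)
}

#' Run the full three-phase prediction for one or more cases
#'
#' Phase 1 on the whole compressed volume, then per landmark a width-`phase2`
#' refinement centred on the phase-1 estimate and a width-`phase3`
#' refinement centred on the phase-2 estimate.  All three phases are
#' recorded.
#'
#' @param volumes a [case_volume()] or list of them.
#' @param models result of [load_models()] (or an equivalent list with
#'   elements `phase1`, `phase2` and `phase3`, the latter two named by
#'   landmark code) -- 33 model handles in total.
#' @param config a [craniomark_config()].
#' @return A list of `prediction_set` objects (one per case), each holding
#'   `case_id`, `phase1`/`phase2`/`phase3` 16 x 3 coordinate matrices and
#'   the crop windows used at each refinement.
#' @export
run_full <- function(volumes, models, config = craniomark_config()) {
  if (inherits(volumes, "case_volume")) volumes <- list(volumes)
  codes <- landmark_catalog()$code
  missing2 <- setdiff(codes, names(models$phase2))
  missing3 <- setdiff(codes, names(models$phase3))
  if (is.null(models$phase1) || length(missing2) || length(missing3)) {
    stop("configuration error: need 1 phase-1 and 16 + 16 refinement models")
  }
  lapply(volumes, function(volume) {
    v <- prepare_volume(volume, config)
    p1 <- predict_phase1(models$phase1, volume, config)
    p2 <- p1 * NA_real_
    p3 <- p1 * NA_real_
    w2 <- list()
    w3 <- list()
    for (code in codes) {
      r2 <- refine(v, p1[code, ], config$crop_width[["phase2"]],
                   models$phase2[[code]], config)
      p2[code, ] <- r2$coords
      w2[[code]] <- r2$window
      r3 <- refine(v, p2[code, ], config$crop_width[["phase3"]],
                   models$phase3[[code]], config)
      p3[code, ] <- r3$coords
      w3[[code]] <- r3$window
    }
    structure(list(case_id = volume$case_id, phase1 = p1, phase2 = p2,
                   phase3 = p3, windows2 = w2, windows3 = w3),
              class = "prediction_set")
  })
}

#' @export
print.prediction_set <- function(x, ...) {
  cat("prediction_set for ", x$case_id, ": 16 landmarks x 3 phases\n",
      sep = "")
  invisible(x)
}

#' Per-axis and 3D localization errors
#'
#' For every (case, landmark, phase) computes the absolute per-axis gaps and
#' the 3D Euclidean distance `sqrt(dx^2 + dy^2 + dz^2)` between prediction
#' and ground truth, in px.
#'
#' @param preds list of `prediction_set`s (from [run_full()]).
#' @param truth list of [landmark_table()]s covering the same case ids.
#' @return A data.frame of class `error_report` with columns `case_id`,
#'   `landmark`, `phase`, `dx`, `dy`, `dz`, `d3`.
#' @export
evaluate <- function(preds, truth) {
  truth_ids <- vapply(truth, case_id_of, character(1))
  rows <- lapply(preds, function(ps) {
    j <- match(ps$case_id, truth_ids)
    if (is.na(j)) stop("input error: no ground truth for case ", ps$case_id)
    gt <- unclass(truth[[j]])
    do.call(rbind, lapply(c("phase1", "phase2", "phase3"), function(ph) {
      delta <- abs(ps[[ph]] - gt)
      data.frame(case_id = ps$case_id,
                 landmark = rownames(gt),
                 phase = ph,
                 dx = delta[, 1], dy = delta[, 2], dz = delta[, 3],
                 d3 = sqrt(rowSums(delta^2)),
                 row.names = NULL)
    }))
  })
  structure(do.call(rbind, rows), class = c("error_report", "data.frame"))
}

#' Summaries of an error report
#'
#' Pools all case x landmark observations and reports mean, median and
#' sample standard deviation of the 3D error per phase (`by = "phase"`), per
#' landmark within phase (`by = "landmark"`), or of the per-axis absolute
#' errors within phase (`by = "axis"`).
#'
#' @param report an `error_report` from [evaluate()].
#' @param by grouping: `"phase"`, `"landmark"` or `"axis"`.
#' @return A data.frame of summary statistics.
#' @export
summarize_errors <- function(report, by = c("phase", "landmark", "axis")) {
  by <- match.arg(by)
  stat <- function(v) c(mean = mean(v), median = stats::median(v),
                        stdev = stats::sd(v))
  if (by == "phase") {
    out <- do.call(rbind, lapply(split(report$d3, report$phase), stat))
    data.frame(phase = rownames(out), out, row.names = NULL)
  } else if (by == "landmark") {
    grp <- interaction(report$phase, report$landmark, sep = ":")
    out <- do.call(rbind, lapply(split(report$d3, grp), stat))
    ph <- sub(":.*", "", rownames(out))
    lm <- sub(".*:", "", rownames(out))
    data.frame(phase = ph, landmark = lm, out, row.names = NULL)
  } else {
    rows <- lapply(c("dx", "dy", "dz"), function(ax) {
      out <- do.call(rbind, lapply(split(report[[ax]], report$phase), stat))
      data.frame(phase = rownames(out), axis = sub("d", "", ax), out,
                 row.names = NULL)
    })
    do.call(rbind, rows)
  }
}

#' Conover-Iman pairwise comparisons after Kruskal-Wallis
#'
#' Rank-based post-hoc test: pooled ranks feed t statistics on rank-sum
#' means with the Kruskal-Wallis statistic in the variance term,
#' `t = (Ri. - Rj.) / sqrt(S2 * (N - 1 - H) / (N - k) * (1/ni + 1/nj))`
#' on `N - k` degrees of freedom, two-sided, Holm-adjusted.
#'
#' @param error_groups named list of >= 2 numeric samples (each >= 2
#'   observations), e.g. the per-phase 3D errors.
#' @param p_adjust adjustment method passed to [stats::p.adjust()].
#' @return Symmetric matrix of adjusted p-values with unit diagonal.
#' @export
compare_groups <- function(error_groups, p_adjust = "holm") {
  k <- length(error_groups)
  if (k < 2L) stop("need at least two groups")
  if (any(lengths(error_groups) < 2L)) {
    stop("each group needs at least two observations")
  }
  if (is.null(names(error_groups))) {
    names(error_groups) <- paste0("group", seq_len(k))
  }
  x <- unlist(error_groups, use.names = FALSE)
  g <- factor(rep(names(error_groups), lengths(error_groups)),
              levels = names(error_groups))
  N <- length(x)
  r <- rank(x)
  n_i <- as.numeric(table(g))
  rbar <- tapply(r, g, mean)
  S2 <- (sum(r^2) - N * (N + 1)^2 / 4) / (N - 1)
  if (S2 <= 0) {
    warning("degenerate groups: all observations tied")
    p <- matrix(1, k, k, dimnames = list(names(error_groups),
                                         names(error_groups)))
    return(p)
  }
  H <- unname(stats::kruskal.test(x, g)$statistic)
  fac <- max(N - 1 - H, 0) / (N - k)
  praw <- matrix(NA_real_, k, k)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      se <- sqrt(S2 * fac * (1 / n_i[i] + 1 / n_i[j]))
      tij <- if (se == 0) Inf * sign(rbar[i] - rbar[j]) else
        (rbar[i] - rbar[j]) / se
      praw[i, j] <- 2 * stats::pt(-abs(tij), df = N - k)
    }
  }
  padj <- praw
  padj[upper.tri(padj)] <- stats::p.adjust(praw[upper.tri(praw)],
                                           method = p_adjust)
  padj[lower.tri(padj)] <- t(padj)[lower.tri(padj)]
  diag(padj) <- 1
  dimnames(padj) <- list(names(error_groups), names(error_groups))
  padj
}

#' Save / load prediction sets as CSV
#'
#' Long format: `case_id, code, phase, x, y, z` -- the landmark-table format
#' plus a phase column.
#'
#' @param preds list of `prediction_set`s.
#' @param path CSV path.
#' @return `read_predictions()`: a list of `prediction_set`s (without crop
#'   windows, which are inference-time artifacts).
#' @export
write_predictions <- function(preds, path) {
  rows <- lapply(preds, function(ps) {
    do.call(rbind, lapply(c("phase1", "phase2", "phase3"), function(ph) {
      data.frame(case_id = ps$case_id, code = rownames(ps[[ph]]), phase = ph,
                 x = ps[[ph]][, 1], y = ps[[ph]][, 2], z = ps[[ph]][, 3],
                 row.names = NULL)
    }))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(case_id = "character"))
  codes <- landmark_catalog()$code
  lapply(unique(df$case_id), function(id) {
    sets <- lapply(c("phase1", "phase2", "phase3"), function(ph) {
      rows <- df[df$case_id == id & df$phase == ph, ]
      rows <- rows[match(codes, rows$code), ]
      m <- as.matrix(rows[, c("x", "y", "z")])
      dimnames(m) <- list(codes, c("x", "y", "z"))
      m
    })
    structure(list(case_id = id, phase1 = sets[[1]], phase2 = sets[[2]],
                   phase3 = sets[[3]], windows2 = NULL, windows3 = NULL),
              class = "prediction_set")
  })
}

# ---- full-system training ---------------------------------------------------

#' Train the complete 33-network system
#'
#' Trains the phase-1 whole-volume regressor plus one phase-2 and one
#' phase-3 refinement model per landmark (1 + 16 + 16 = 33) and persists
#' each as a weights file (`phase1.w`, `phase2_L01.w`, ..., `phase3_L16.w`)
#' in `models_dir`.
#'
#' @param volumes training [case_volume()]s.
#' @param tables matching [landmark_table()]s.
#' @param config a [craniomark_config()]; supplies crop widths, shift grids,
#'   batch sizes, epochs, learning rate and `width_scale`.
#' @param models_dir output directory for the 33 weights files.
#' @param verbose print progress.
#' @return Invisibly, the character vector of the 33 weights paths.
#' @export
train_full_system <- function(volumes, tables, config = craniomark_config(),
                              models_dir, verbose = FALSE) {
  dir.create(models_dir, recursive = TRUE, showWarnings = FALSE)
  codes <- landmark_catalog()$code
  prepared <- lapply(volumes, prepare_volume, config = config)
  say <- function(...) if (verbose) message(...)

  say("phase 1: whole-volume regressor")
  ds1 <- build_phase1_dataset(volumes, tables, config)
  m1 <- build_regressor(
    regressor_spec(c(config$phase1_size, config$phase1_size, config$depth),
                   48L, config$width_scale),
    seed = config$seed
  )
  train_regressor(m1, ds1, batch_size = config$batch_size[["phase1"]],
                  epochs = config$epochs[["phase1"]], lr = config$lr,
                  seed = config$seed,
                  weights_path = file.path(models_dir, "phase1.w"))

  for (phase in c("phase2", "phase3")) {
    width <- config$crop_width[[phase]]
    grid <- make_shift_grid(config$max_shift[[phase]],
                            config$shift_step[[phase]])
    for (li in seq_along(codes)) {
      code <- codes[li]
      say(phase, " refinement: ", code)
      ds <- build_refinement_dataset(prepared, tables, code, width, grid,
                                     depth = config$depth,
                                     threshold = config$threshold)
      m <- build_regressor(
        regressor_spec(c(width, width, config$depth), 3L, config$width_scale),
        seed = config$seed + 100L * match(phase, c("phase2", "phase3")) + li
      )
      train_regressor(m, ds, batch_size = config$batch_size[[phase]],
                      epochs = config$epochs[[phase]], lr = config$lr,
                      seed = config$seed + 1000L *
                        match(phase, c("phase2", "phase3")) + li,
                      weights_path = file.path(models_dir,
                                               paste0(phase, "_", code, ".w")))
    }
  }
  invisible(model_paths(models_dir))
}

model_paths <- function(models_dir) {
  codes <- landmark_catalog()$code
  c(file.path(models_dir, "phase1.w"),
    file.path(models_dir, paste0("phase2_", codes, ".w")),
    file.path(models_dir, paste0("phase3_", codes, ".w")))
}

#' Load the 33 trained model handles
#'
#' @param models_dir directory holding `phase1.w`, `phase2_L01.w`, ...,
#'   `phase3_L16.w`.
#' @return A list with `phase1` (one model) and `phase2`/`phase3` (lists of
#'   16 models named by landmark code).
#' @export
load_models <- function(models_dir) {
  paths <- model_paths(models_dir)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("configuration error: missing model file(s): ",
         paste(basename(missing), collapse = ", "))
  }
  codes <- landmark_catalog()$code
  list(phase1 = load_weights(file.path(models_dir, "phase1.w")),
       phase2 = setNames(lapply(codes, function(cd)
         load_weights(file.path(models_dir, paste0("phase2_", cd, ".w")))),
         codes),
       phase3 = setNames(lapply(codes, function(cd)
         load_weights(file.path(models_dir, paste0("phase3_", cd, ".w")))),
         codes))
}

#' Desk-scale phantom benchmark of the three-phase system
#'
#' End-to-end study at desk scale: generates a phantom cohort, trains the 33
#' networks on the training cases, runs the three-phase prediction on the
#' held-out cases, and evaluates localization errors and the phase-1 vs
#' phase-3 Conover comparison.
#'
#' @param seed benchmark seed (phantom cohort, splits, weights, shuffling).
#' @param n_train,n_test cohort sizes.
#' @param config a desk-scale [craniomark_config()].
#' @param models_dir where to persist the 33 weights files; a temporary
#'   directory by default.
#' @param verbose print progress.
#' @return A list with `report` (the [evaluate()] error report), `summary`
#'   (per-phase 3D error summary), `pvalues` (Conover matrix across the
#'   three phases), and `models_dir`.
#' @export
run_desk_benchmark <- function(seed = 0L, n_train = 20L, n_test = 10L,
                               config = craniomark_config("desk", seed = seed),
                               models_dir = file.path(tempdir(),
                                                      paste0("craniomark_models_",
                                                             seed)),
                               verbose = FALSE) {
  spec <- phantom_spec(seed = seed, n_cases = n_train + n_test,
                       grid = c(config$frame, config$frame, config$depth),
                       in_plane_mm = config$in_plane_mm,
                       slice_mm = config$slice_mm,
                       threshold = config$threshold)
  cohort <- generate_cohort(spec)
  idx <- split_train_test(seq_along(cohort$volumes), n_train, n_test,
                          seed = seed)
  train_full_system(cohort$volumes[idx$train], cohort$tables[idx$train],
                    config, models_dir, verbose = verbose)
  models <- load_models(models_dir)
  preds <- run_full(cohort$volumes[idx$test], models, config)
  report <- evaluate(preds, cohort$tables[idx$test])
  groups <- split(report$d3, report$phase)
  list(report = report,
       summary = summarize_errors(report, by = "phase"),
       pvalues = compare_groups(groups),
       models_dir = models_dir)
}
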