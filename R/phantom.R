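#' Specification of the synthetic skull phantom cohort
#'
#' The phantom emulates the features of a craniofacial CT cohort that the
#' three-phase pipeline depends on: binarizable bone-like structures (an
#' ellipsoidal vault shell, a half-torus mandibular arch joined to the vault
#' by two rami, and a distinct marker knob at each of the 16 catalog
#' landmarks), exact landmark ground truth, head centres scattered more in y
#' than in x, and per-structure stored-value bands that straddle the bone
#' threshold.  All lengths are fractions of the grid, so scaling the grid by
#' *s* scales every ground-truth coordinate by *s* exactly.
#'
#' @param seed integer cohort seed; each case uses an independent stream
#'   derived from `(seed, case_index)`, so cohorts are order-independent.
#' @param n_cases number of cases.
#' @param grid `c(width, height, depth)` voxels.
#' @param in_plane_mm in-plane spacing; default maps the frame to 500 mm.
#' @param slice_mm slice interval; default makes the z extent (in px) equal
#'   the frame width, i.e. a z step of `grid[1] / grid[3]` px.
#' @param skull_radii list of `x`, `y`, `z` radius ranges as fractions of the
#'   half-frame (x, y) and half-z-extent.
#' @param shell_thickness relative thickness of the vault shell.
#' @param mandible_arc list: `radius` range (fraction of the x radius),
#'   `angle` range (rad from the anterior midline to each gonion), `tube`
#'   tube radius (fraction of width), `drop` (gonion depth below the vault
#'   centre, fraction of the z radius), `anterior_offset` (arch centre shift
#'   towards the face, fraction of height).
#' @param jitter per-axis head-centre scatter in px at the 96-px reference
#'   width (scaled with the grid); the y scatter must exceed the x scatter.
#' @param asymmetry sd of the independent perturbation of each bilateral
#'   landmark, px at reference width.
#' @param marker_radius landmark marker-knob radius, fraction of width.
#' @param intensity list of `bone` and `soft` stored-value ranges; bone must
#'   lie entirely above and soft tissue entirely below `threshold`.
#' @param threshold stored-value bone threshold the phantom must respect.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(seed = 0L, n_cases = 120L, grid = c(96L, 96L, 24L),
                         in_plane_mm = 500 / grid[1],
                         slice_mm = in_plane_mm * grid[1] / grid[3],
                         skull_radii = list(x = c(0.60, 0.68),
                                            y = c(0.68, 0.76),
                                            z = c(0.80, 0.88)),
                         shell_thickness = 0.12,
                         mandible_arc = list(radius = c(0.75, 0.83),
                                             angle = c(1.75, 1.90),
                                             tube = 0.025,
                                             drop = 0.80,
                                             anterior_offset = 0.05),
                         jitter = c(x = 1, y = 3, z = 1),
                         asymmetry = 0.4,
                         marker_radius = 0.032,
                         intensity = list(bone = c(1500, 2500),
                                          soft = c(100, 800)),
                         threshold = 1100L) {
  if (min(intensity$bone) <= threshold) {
    stop("parameter error: bone intensity must lie above the threshold")
  }
  if (max(intensity$soft) >= threshold) {
    stop("parameter error: soft-tissue intensity must lie below the threshold")
  }
  if (jitter[["y"]] <= jitter[["x"]]) {
    stop("parameter error: y jitter must exceed x jitter")
  }
  structure(list(seed = as.integer(seed), n_cases = as.integer(n_cases),
                 grid = as.integer(grid), in_plane_mm = in_plane_mm,
                 slice_mm = slice_mm, skull_radii = skull_radii,
                 shell_thickness = shell_thickness,
                 mandible_arc = mandible_arc, jitter = jitter,
                 asymmetry = asymmetry, marker_radius = marker_radius,
                 intensity = intensity, threshold = as.integer(threshold)),
            class = "phantom_spec")
}

# Fixed landmark geometry: unit directions on the vault shell, interior
# offsets (fractions of the radii), or positions on the mandibular arch.
phantom_feature_table <- function() {
  d <- data.frame(
    code = sprintf("L%02d", 1:16),
    type = c("shell", "shell", "mandible", "shell", "shell", "shell",
             "mandible", "shell", "shell", "interior", "mandible", "shell",
             "shell", "shell", "interior", "interior"),
    ux = c(0, 0, 1, 0.62, 0.97, 0.42, 0, 0, 0, 0, -1, -0.62, -0.97, -0.42,
           0, 0),
    uy = c(-0.99, -0.97, 0, -0.70, 0.02, -0.78, 0, -0.92, 0.98, -0.35, 0,
           -0.70, 0.02, -0.78, -0.05, -0.30),
    uz = c(-0.28, -0.14, 0, -0.12, -0.30, 0.12, 0, 0.10, -0.20, -0.30, 0,
           -0.12, -0.30, 0.12, -0.10, 0.22),
    stringsAsFactors = FALSE
  )
  d
}

case_seed <- function(seed, case_index) {
  (as.numeric(seed) * 1000003 + as.numeric(case_index) * 7919) %% 2147483647
}

#' Generate one phantom case
#'
#' Deterministic for a given `(spec$seed, case_index)`.  The returned
#' landmark table holds the exact analytic marker centres; binarizing the
#' volume at `spec$threshold` leaves bone at every marker, so each landmark's
#' 3 x 3 in-plane neighbourhood on its nearest slice contains bone.
#'
#' @param spec a [phantom_spec()].
#' @param case_index 0-based case index.
#' @return A list with `volume` (a [case_volume()]) and `table`
#'   (a [landmark_table()]).
#' @export
generate_case <- function(spec, case_index) {
  stopifnot(inherits(spec, "phantom_spec"))
  W <- spec$grid[1]; H <- spec$grid[2]; D <- spec$grid[3]
  z_step <- spec$slice_mm / spec$in_plane_mm
  z_ext <- D * z_step
  sc <- W / 96  # px scale factor relative to the reference width

  with_seed(case_seed(spec$seed, case_index), {
    # ---- geometry draws (fixed count and order) ----
    jc <- pmin(pmax(rnorm(3), -2.5), 2.5)  # clamped so geometry stays in-grid
    ru <- runif(3)
    au <- rnorm(24)
    mu <- runif(2)

    cx <- W / 2 + jc[1] * spec$jitter[["x"]] * sc
    cy <- H / 2 + jc[2] * spec$jitter[["y"]] * sc
    cz <- z_ext * 0.52 + jc[3] * spec$jitter[["z"]] * sc
    rr <- function(range, u) range[1] + u * diff(range)
    rx <- rr(spec$skull_radii$x, ru[1]) * W / 2
    ry <- rr(spec$skull_radii$y, ru[2]) * H / 2
    rz <- rr(spec$skull_radii$z, ru[3]) * z_ext / 2

    arc <- spec$mandible_arc
    r_m <- rr(arc$radius, mu[1]) * rx
    phi_max <- rr(arc$angle, mu[2])
    cy_m <- cy - arc$anterior_offset * H
    z_g <- cz - arc$drop * rz
    tube_r <- arc$tube * W

    s0 <- 1 - spec$shell_thickness / 2  # mid-shell surface
    feat <- phantom_feature_table()
    lm <- matrix(NA_real_, 16, 3)
    for (i in seq_len(16)) {
      ty <- feat$type[i]
      if (ty == "shell") {
        d3 <- c(feat$ux[i], feat$uy[i], feat$uz[i])
        t <- s0 / sqrt((d3[1] / rx)^2 + (d3[2] / ry)^2 + (d3[3] / rz)^2)
        lm[i, ] <- c(cx, cy, cz) + t * d3
      } else if (ty == "interior") {
        lm[i, ] <- c(cx + feat$ux[i] * rx, cy + feat$uy[i] * ry,
                     cz + feat$uz[i] * rz)
      } else {  # mandible arch: ux = +1 left gonion, -1 right, 0 menton
        phi <- feat$ux[i] * phi_max
        lm[i, ] <- c(cx + r_m * sin(phi), cy_m - r_m * cos(phi), z_g)
      }
    }
    # independent small perturbation of each bilateral landmark
    pairs <- which(!is.na(landmark_catalog()$mirror))
    lm[pairs, ] <- lm[pairs, ] +
      matrix(au, ncol = 3) * spec$asymmetry * sc
    rownames(lm) <- feat$code

    marker_r <- spec$marker_radius * W
    margin <- max(marker_r, 2)
    in_x <- lm[, 1] >= margin & lm[, 1] <= W - 1 - margin
    in_y <- lm[, 2] >= margin & lm[, 2] <= H - 1 - margin
    in_z <- lm[, 3] >= 0 & lm[, 3] <= z_ext - 1
    if (!all(in_x & in_y & in_z) ||
        cx + rx > W - 2 || cx - rx < 1 || cy + ry > H - 2 || cy - ry < 1) {
      stop("parameter error: phantom geometry exceeds the grid")
    }

    # porion/gonion anchors for the two rami (left = L03 -> L05, right = L11 -> L13)
    ram <- list(list(from = lm["L03", ], to = lm["L05", ]),
                list(from = lm["L11", ], to = lm["L13", ]))
    ramus_r <- max(0.019 * W, 1.6)

    # ---- rendering ----
    # each slice samples its geometry over the full slab [z - h, z + h],
    # emulating the partial-volume averaging of a thick CT slice; this also
    # keeps thin oblique structures 6-connected across coarse z grids
    xg <- matrix(0:(W - 1), W, H)
    yg <- matrix(0:(H - 1), W, H, byrow = TRUE)
    pixels <- array(0L, c(W, H, D))
    inner2 <- (1 - spec$shell_thickness)^2
    h <- z_step / 2
    for (k in 0:(D - 1)) {
      z <- k * z_step
      a2 <- ((xg - cx) / rx)^2 + ((yg - cy) / ry)^2
      # ellipsoid shell over the slab: nearest and farthest z of the slab
      zz_near <- min(max(cz, z - h), z + h)
      zz_far <- if (abs(z - h - cz) > abs(z + h - cz)) z - h else z + h
      s_min <- a2 + ((zz_near - cz) / rz)^2
      s_max <- a2 + ((zz_far - cz) / rz)^2
      bone <- s_min <= 1 & s_max >= inner2
      soft <- s_max < inner2
      # mandibular arch (half torus in the z_g plane)
      dz_arc <- max(0, abs(z - z_g) - h)
      if (dz_arc < tube_r) {
        half <- sqrt(tube_r^2 - dz_arc^2)
        rad <- sqrt((xg - cx)^2 + (yg - cy_m)^2)
        phi <- atan2(xg - cx, cy_m - yg)
        bone <- bone | (abs(rad - r_m) <= half & abs(phi) <= phi_max)
      }
      # rami: discs at both slab ends of each gonion-porion segment
      for (rm in ram) {
        z0 <- rm$from[3]; z1 <- rm$to[3]
        zlo <- min(z0, z1); zhi <- max(z0, z1)
        if (z + h >= zlo && z - h <= zhi) {
          for (ze in unique(c(min(max(z - h, zlo), zhi),
                              min(max(z + h, zlo), zhi)))) {
            tt <- if (abs(z1 - z0) < 1e-9) 0.5 else (ze - z0) / (z1 - z0)
            px0 <- rm$from[1] + tt * (rm$to[1] - rm$from[1])
            py0 <- rm$from[2] + tt * (rm$to[2] - rm$from[2])
            bone <- bone | ((xg - px0)^2 + (yg - py0)^2 <= ramus_r^2)
          }
        }
      }
      # landmark marker knobs
      for (i in seq_len(16)) {
        dzl <- max(0, abs(z - lm[i, 3]) - h)
        if (dzl < marker_r) {
          disc2 <- marker_r^2 - dzl^2
          bone <- bone | ((xg - lm[i, 1])^2 + (yg - lm[i, 2])^2 <= disc2)
        }
      }
      soft <- soft & !bone
      sl <- matrix(0L, W, H)
      nb <- sum(bone); ns <- sum(soft)
      if (nb) sl[bone] <- as.integer(round(runif(nb, spec$intensity$bone[1],
                                                 spec$intensity$bone[2])))
      if (ns) sl[soft] <- as.integer(round(runif(ns, spec$intensity$soft[1],
                                                 spec$intensity$soft[2])))
      pixels[, , k + 1] <- sl
    }
    id <- sprintf("case_%03d", case_index)
    list(volume = case_volume(pixels, id, (0:(D - 1)) * spec$slice_mm,
                              in_plane_mm = spec$in_plane_mm,
                              slice_mm = spec$slice_mm),
         table = landmark_table(lm, id))
  })
}

#' Generate a phantom cohort
#'
#' @param spec a [phantom_spec()].
#' @param indices 0-based case indices; defaults to `0:(n_cases - 1)`.
#' @return A list with `volumes` and `tables`, each of length `n_cases`.
#' @export
generate_cohort <- function(spec, indices = seq_len(spec$n_cases) - 1L) {
  stopifnot(inherits(spec, "phantom_spec"), length(indices) >= 1L)
  cases <- lapply(indices, function(i) generate_case(spec, i))
  list(volumes = lapply(cases, `[[`, "volume"),
       tables = lapply(cases, `[[`, "table"))
}

#' Write a phantom cohort as DICOM series plus a landmark CSV
#'
#' Produces exactly the on-disk layout the ingestion modules consume: one
#' DICOM directory per case under `directory` and a single `landmarks.csv`.
#'
#' @param cohort result of [generate_cohort()].
#' @param directory output directory.
#' @return `directory`, invisibly.
#' @export
write_cohort <- function(cohort, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  for (v in cohort$volumes) {
    write_series(v, file.path(directory, v$case_id))
  }
  write_landmarks(cohort$tables, file.path(directory, "landmarks.csv"))
  invisible(directory)
}
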