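test_that("shift grids are half-open Cartesian lattices", {
  g <- make_shift_grid(30, 10)
  expect_identical(nrow(g$offsets), 36L)
  expect_true(any(g$offsets[, 1] == -30 & g$offsets[, 2] == -30))
  expect_false(any(g$offsets[, 1] == 30))
  expect_false(any(g$offsets[, 2] == 30))
  expect_identical(nrow(make_shift_grid(15, 5)$offsets), 36L)
  g2 <- make_shift_grid(10, 10)
  expect_identical(nrow(g2$offsets), 4L)
  expect_setequal(unique(g2$offsets[, 1]), c(-10, 0))
  expect_error(make_shift_grid(30, 7), "parameter error")
  expect_error(make_shift_grid(30, 0), "parameter error")
})

test_that("shift-grid cardinality follows (2 max_shift / step)^2", {
  for (ms in c(6, 12, 30)) {
    for (st in c(1, 2, 3, 6)) {
      expect_identical(nrow(make_shift_grid(ms, st)$offsets),
                       as.integer((2 * ms / st)^2))
    }
  }
})

test_that("crop windows are placed at round(center) - width/2", {
  vol <- random_volume(1, W = 512L, H = 512L, n = 2L)
  cr <- crop_stack(vol, c(256, 256), 100L, depth = 4L)
  expect_identical(cr$window$x0, 206L)
  expect_identical(cr$window$y0, 206L)
  cr2 <- crop_stack(vol, c(10, 256), 100L, depth = 4L)
  expect_identical(cr2$window$x0, -40L)
  # columns with global x < 0 are zero-filled
  expect_identical(sum(cr2$stack$voxels[1:40, , ]), 0L)
})

test_that("crop_stack equals a naive per-pixel copy on random windows", {
  vol <- random_volume(2, W = 60L, H = 60L, n = 3L)
  bin <- binarize(vol$pixels, 1100L)
  set.seed(3)
  for (rep in 1:100) {
    center <- runif(2, -30, 90)  # includes fully and partly out-of-bounds
    width <- sample(c(10L, 20L), 1)
    cr <- crop_stack(vol, center, width, depth = 4L)
    x0 <- cr$window$x0
    y0 <- cr$window$y0
    oracle <- array(0L, c(width, width, 4L))
    for (lx in seq_len(width)) for (ly in seq_len(width)) {
      gx <- x0 + lx - 1L
      gy <- y0 + ly - 1L
      if (gx >= 0 && gx < 60 && gy >= 0 && gy < 60) {
        oracle[lx, ly, 1:3] <- bin[gx + 1L, gy + 1L, ]
      }
    }
    expect_identical(cr$stack$voxels, oracle)
    # zero conservation: the crop can never contain more bone than the volume
    expect_lte(sum(cr$stack$voxels), sum(bin))
  }
})

test_that("a single bone voxel lands at the window-mapped local position", {
  px <- array(0L, c(60, 60, 3))
  px[26, 26, 2] <- 4000L  # global (25, 25), slice index 1
  vol <- case_volume(px, "one", (0:2) * 5)
  cr <- crop_stack(vol, c(25, 25), 20L, depth = 3L)
  expect_identical(cr$window$x0, 15L)
  expect_identical(sum(cr$stack$voxels), 1L)
  expect_identical(cr$stack$voxels[11, 11, 2], 1L)  # local (10, 10)
})

test_that("local targets follow the crop-shift rule", {
  w <- crop_window(250, 250, 100)
  expect_equal(local_target(c(300, 300, 40), w), c(50, 50, 40))
  # crop shifted +10 in x: origin moves +10, target drops to 40
  w_shift <- crop_window(260, 250, 100)
  expect_equal(local_target(c(300, 300, 40), w_shift), c(40, 50, 40))
  w50 <- crop_window(275, 275, 50)
  expect_equal(local_target(c(300, 300, 40), w50), c(25, 25, 40))
})

test_that("remap_to_global inverts local_target exactly", {
  expect_equal(remap_to_global(c(50, 50, 40), crop_window(206, 206, 100)),
               c(256, 256, 40))
  set.seed(4)
  for (rep in 1:1000) {
    p <- c(runif(2, -100, 600), runif(1, 0, 400))
    w <- crop_window(sample(-200:600, 1), sample(-200:600, 1),
                     sample(c(50L, 100L), 1))
    expect_identical(remap_to_global(local_target(p, w), w), p)
  }
})

test_that("refinement datasets enumerate cases x offsets with shifted targets", {
  spec <- tiny_phantom_spec(seed = 2, n_cases = 2)
  coh <- generate_cohort(spec)
  # integer landmark coordinates make the target arithmetic exact
  tabs <- lapply(coh$tables, function(tb) {
    landmark_table(round(unclass(tb)), attr(tb, "case_id"))
  })
  g <- make_shift_grid(10, 10)
  ds <- build_refinement_dataset(coh$volumes, tabs, "L08", 12L, g,
                                 depth = 12L)
  expect_s3_class(ds, "refinement_dataset")
  expect_length(ds$examples, 2L * 4L)
  ds1 <- build_refinement_dataset(coh$volumes[1], tabs[1], "L08", 12L, g,
                                  depth = 12L)
  expect_length(ds1$examples, 4L)
  for (ex in ds$examples) {
    lm <- tabs[[match(ex$case_id, vapply(tabs, attr, "", "case_id"))]]["L08", ]
    expect_equal(ex$target, unname(local_target(lm, ex$window)))
    expect_equal(dim(ex$stack$voxels), c(12L, 12L, 12L))
  }
  # with integer landmarks the in-plane targets are width/2 - shift:
  # shifts {-10, 0} give local targets {16, 6} on each axis
  t1 <- vapply(ds1$examples, function(e) e$target[1], numeric(1))
  expect_setequal(unique(t1), c(16, 6))
  expect_error(build_refinement_dataset(coh$volumes, tabs, "L99", 12L, g),
               "input error")
})

test_that("refinement datasets serialize and reload", {
  spec <- tiny_phantom_spec(seed = 5, n_cases = 1)
  coh <- generate_cohort(spec)
  ds <- build_refinement_dataset(coh$volumes, coh$tables, "L15", 8L,
                                 make_shift_grid(4, 4), depth = 12L)
  f <- tempfile(fileext = ".rds")
  write_dataset(ds, f)
  back <- read_dataset(f)
  expect_identical(back$examples[[2]]$stack$voxels, ds$examples[[2]]$stack$voxels)
  expect_identical(back$examples[[3]]$target, ds$examples[[3]]$target)
  bad <- tempfile(fileext = ".rds")
  saveRDS(list(1, 2), bad)
  expect_error(read_dataset(bad), "format error")
})
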