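test_that("binarize thresholds stored values with the >= convention", {
  m <- matrix(c(4000, 1100, 1099, 0), 2, 2)
  b <- binarize(m)
  expect_identical(b, matrix(c(1L, 1L, 0L, 0L), 2, 2))
  expect_identical(binarize(matrix(0, 3, 3)), matrix(0L, 3, 3))
})

test_that("binarize agrees with an elementwise comparison oracle", {
  set.seed(7)
  for (rep in 1:5) {
    x <- matrix(sample.int(4100, 100, replace = TRUE) - 1L, 10, 10)
    got <- binarize(x, 1100)
    oracle <- matrix(0L, 10, 10)
    for (i in 1:10) for (j in 1:10) {
      if (x[i, j] >= 1100) oracle[i, j] <- 1L
    }
    expect_identical(got, oracle)
    # idempotence: re-binarizing the mask at threshold 1 is a no-op
    expect_identical(binarize(got, 1L), got)
  }
})

test_that("calibration cross writes 4000 on row and column 255 of the caudal slice", {
  px <- array(0L, c(512, 512, 2))
  vol <- case_volume(px, "c1", c(0, 5))
  out <- add_calibration_cross(vol)
  # 0-based (255, 10) and (10, 255)
  expect_identical(out$pixels[256, 11, 1], 4000L)
  expect_identical(out$pixels[11, 256, 1], 4000L)
  expect_identical(out$pixels[255, 11, 1], 0L)  # (254, 10) untouched
  expect_identical(out$pixels[, , 2], px[, , 2])  # other slices untouched
})

test_that("calibration cross modifies exactly 2S - 1 pixels of a clean slice", {
  for (S in c(512L, 300L)) {
    px <- array(0L, c(S, S, 1))
    vol <- case_volume(px, "c", 0)
    out <- add_calibration_cross(vol)
    changed <- sum(out$pixels != vol$pixels)  # brute-force diff
    expect_identical(changed, 2L * S - 1L)
  }
})

test_that("calibration cross rejects slices smaller than the cross index", {
  vol <- case_volume(array(0L, c(200, 200, 1)), "small", 0)
  expect_error(add_calibration_cross(vol), "index error")
})

test_that("area compression preserves constants and the identity case", {
  img <- matrix(100, 512, 512)
  out <- compress_slice(img, 96)
  expect_equal(dim(out), c(96L, 96L))
  expect_equal(out, matrix(100, 96, 96), tolerance = 1e-12)
  expect_equal(compress_slice(img, 512), img)
  expect_error(compress_slice(img, 0), "parameter error")
  expect_error(compress_slice(matrix(0, 4, 5), 2), "square")
})

test_that("a bright source row maps to the area-scaled output row", {
  img <- matrix(0, 512, 512)
  img[256, ] <- 1000  # 0-based x = 255
  out <- compress_slice(img, 96)
  # 255 * 96 / 512 = 47.8 -> 0-based output row 47
  expect_identical(which.max(rowMeans(out)), 48L)
})

test_that("compress_slice equals a naive per-cell area-average oracle", {
  set.seed(11)
  n_src <- 32L; n_tgt <- 6L
  img <- matrix(runif(n_src^2, 0, 4071), n_src, n_src)
  got <- compress_slice(img, n_tgt)
  r <- n_src / n_tgt
  oracle <- matrix(0, n_tgt, n_tgt)
  for (i in seq_len(n_tgt)) for (j in seq_len(n_tgt)) {
    acc <- 0
    for (si in seq_len(n_src)) for (sj in seq_len(n_src)) {
      wx <- max(0, min(i * r, si) - max((i - 1) * r, si - 1))
      wy <- max(0, min(j * r, sj) - max((j - 1) * r, sj - 1))
      acc <- acc + wx * wy * img[si, sj]
    }
    oracle[i, j] <- acc / r^2
  }
  expect_equal(got, oracle, tolerance = 1e-10)
})

test_that("phase-1 stacks fill bottom-up and pad the remaining depth with zeros", {
  set.seed(3)
  px <- array(sample.int(4072, 40 * 40 * 5, replace = TRUE) - 1L, c(40, 40, 5))
  vol <- case_volume(px, "c", (0:4) * 5)
  st <- build_phase1_stack(vol, width = 8L, depth = 12L)
  expect_s3_class(st, "binary_stack")
  expect_equal(dim(st$voxels), c(8L, 8L, 12L))
  expect_true(all(st$voxels %in% 0:1))
  expect_identical(sum(st$voxels[, , 6:12]), 0L)  # beyond slice count
  expect_equal(st$scale, 8 / 40)
  # slice i occupies depth index i: compare one layer directly
  expect_identical(st$voxels[, , 3],
                   binarize(compress_slice(px[, , 3], 8L), 1100L))
})

test_that("phase-1 stack conserves emptiness and respects capacity", {
  vol <- case_volume(array(0L, c(16, 16, 3)), "empty", (0:2) * 5)
  st <- build_phase1_stack(vol, 8L, 4L)
  expect_identical(sum(st$voxels), 0L)
  expect_error(build_phase1_stack(vol, 8L, 2L), "capacity error")
})

test_that("a small supra-threshold block survives compress-then-binarize", {
  # 8 x 8 block of bone at full 512 resolution; after 96-px area
  # compression the covered cell averages above threshold
  img <- matrix(0, 512, 512)
  img[200:207, 300:307] <- 4000
  vol <- case_volume(array(as.integer(img), c(512, 512, 1)), "c", 0)
  st <- build_phase1_stack(vol, 96L, 4L)
  expect_gte(sum(st$voxels), 1L)
})

test_that("case_volume validates its invariants", {
  expect_error(case_volume(array(0L, c(4, 5, 1)), "c", 0), "square")
  expect_error(case_volume(array(-1L, c(4, 4, 1)), "c", 0), "non-negative")
  expect_error(case_volume(array(0L, c(4, 4, 2)), "c", c(5, 0)),
               "increasing")
  expect_error(binary_stack(array(2L, c(2, 2, 2))), "0/1")
})
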