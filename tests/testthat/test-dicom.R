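test_that("a DICOM round trip through our writer and reader is exact", {
  set.seed(5)
  px <- matrix(sample.int(4072, 64 * 64, replace = TRUE) - 1L, 64, 64)
  f <- tempfile(fileext = ".dcm")
  write_dicom(f, px, z_mm = 37.5, pixel_spacing_mm = 500 / 512,
              instance_number = 3L, case_id = "rt")
  got <- read_dicom(f)
  expect_identical(got$pixels, px)
  expect_equal(got$pixel_spacing[1], 500 / 512)
  expect_equal(got$slice_position_mm, 37.5)
  expect_identical(got$instance_number, 3L)
})

test_that("pydicom reads files produced by our writer identically", {
  set.seed(6)
  px <- matrix(sample.int(4072, 32 * 32, replace = TRUE) - 1L, 32, 32)
  f <- tempfile(fileext = ".dcm")
  write_dicom(f, px, z_mm = -12.25, pixel_spacing_mm = 0.9765625,
              instance_number = 7L, case_id = "oracle")
  script <- sprintf("
import pydicom, json
ds = pydicom.dcmread(%s)
arr = ds.pixel_array
print(json.dumps({
  'rows': int(ds.Rows), 'cols': int(ds.Columns),
  'spacing': [float(v) for v in ds.PixelSpacing],
  'z': float(ds.ImagePositionPatient[2]),
  'inst': int(ds.InstanceNumber),
  'vals': [int(arr[0, 0]), int(arr[4, 9]), int(arr[31, 31])],
  'total': int(arr.sum())
}))
", deparse(f))
  out <- system2("python", c("-c", shQuote(script)), stdout = TRUE)
  j <- jsonlite::fromJSON(paste(out, collapse = ""))
  expect_identical(j$rows, 32L)
  expect_identical(j$cols, 32L)
  expect_equal(j$spacing, c(0.9765625, 0.9765625))
  expect_equal(j$z, -12.25)
  expect_identical(j$inst, 7L)
  # pydicom indexes [row, col] = [y, x]; ours is pixels[x + 1, y + 1]
  expect_identical(j$vals, c(px[1, 1], px[10, 5], px[32, 32]))
  expect_identical(j$total, sum(px))
})

test_that("our reader parses a file written by pydicom", {
  f <- tempfile(fileext = ".dcm")
  script <- sprintf("
import pydicom
from pydicom.dataset import Dataset, FileMetaDataset
from pydicom.uid import ExplicitVRLittleEndian
import numpy as np
meta = FileMetaDataset()
meta.MediaStorageSOPClassUID = pydicom.uid.SecondaryCaptureImageStorage
meta.MediaStorageSOPInstanceUID = pydicom.uid.generate_uid()
meta.TransferSyntaxUID = ExplicitVRLittleEndian
ds = Dataset()
ds.file_meta = meta
ds.Rows = 16; ds.Columns = 16
ds.SamplesPerPixel = 1; ds.PhotometricInterpretation = 'MONOCHROME2'
ds.BitsAllocated = 16; ds.BitsStored = 16; ds.HighBit = 15
ds.PixelRepresentation = 0
ds.PixelSpacing = ['0.9765625', '0.9765625']
ds.ImagePositionPatient = ['0', '0', '42.5']
ds.InstanceNumber = 9
arr = np.arange(256, dtype=np.uint16).reshape(16, 16)
ds.PixelData = arr.tobytes()
ds.save_as(%s, enforce_file_format=True)
", deparse(f))
  res <- system2("python", c("-c", shQuote(script)), stdout = TRUE,
                 stderr = TRUE)
  got <- read_dicom(f)
  expect_identical(got$rows, 16L)
  # numpy row-major [y, x] -> value at (x, y) is 16 * y + x
  expect_identical(got$pixels[3, 2], 16L * 1L + 2L)
  expect_equal(got$slice_position_mm, 42.5)
  expect_identical(got$instance_number, 9L)
  expect_equal(got$pixel_spacing[1], 0.9765625)
})

test_that("load_series sorts shuffled slices caudal-first by position tag", {
  dir <- file.path(tempdir(), "series_shuffled")
  unlink(dir, recursive = TRUE)
  dir.create(dir)
  set.seed(8)
  z_values <- seq(0, by = 5, length.out = 10)
  shuffled <- sample(z_values)
  # filename order deliberately disagrees with anatomical order
  for (i in seq_along(shuffled)) {
    px <- matrix(0L, 32, 32)
    px[1, 1] <- as.integer(shuffled[i])  # tag each slice with its z
    write_dicom(file.path(dir, sprintf("f%02d.dcm", i)), px,
                z_mm = shuffled[i], instance_number = i, case_id = "s")
  }
  vol <- load_series(dir)
  expect_equal(n_slices_of(vol), 10L)
  expect_equal(vol$slice_positions_mm, z_values)
  expect_equal(as.numeric(vol$pixels[1, 1, ]), z_values)  # pixels follow sort
})

test_that("single-slice directories load and degenerate inputs error", {
  dir <- file.path(tempdir(), "series_single")
  unlink(dir, recursive = TRUE)
  dir.create(dir)
  write_dicom(file.path(dir, "only.dcm"), matrix(1L, 16, 16), z_mm = 0)
  vol <- load_series(dir)
  expect_equal(n_slices_of(vol), 1L)

  empty <- file.path(tempdir(), "series_empty")
  unlink(empty, recursive = TRUE)
  dir.create(empty)
  expect_error(load_series(empty), "input error")
})

test_that("mixed slice dimensions are a format error", {
  dir <- file.path(tempdir(), "series_mixed")
  unlink(dir, recursive = TRUE)
  dir.create(dir)
  write_dicom(file.path(dir, "a.dcm"), matrix(0L, 32, 32), z_mm = 0)
  write_dicom(file.path(dir, "b.dcm"), matrix(0L, 16, 16), z_mm = 5)
  expect_error(load_series(dir), "format error")
})
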