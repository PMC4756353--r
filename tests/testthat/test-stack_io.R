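test_that("physical-to-index mapping floors positions onto the voxel grid", {
  cal <- calibration()
  expect_identical(physical_to_index(0, "z", cal), 0L)
  expect_identical(physical_to_index(25, "z", cal), 25L)
  expect_identical(physical_to_index(10, "x", cal), 41L)
  expect_error(physical_to_index(-1, "x", cal), "non-negative")
  # monotone non-decreasing in position
  pos <- sort(runif(50, 0, 60))
  idx <- physical_to_index(pos, "y", cal)
  expect_true(all(diff(idx) >= 0))
})

test_that("TIFF round trip preserves every voxel exactly", {
  cal <- calibration()
  set.seed(42)
  arr <- array(sample.int(65536, 38 * 24 * 20, replace = TRUE) - 1L,
               c(38, 24, 20))
  stk <- make_stack(arr, cal)
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(stk, path)
  back <- read_stack(path, cal, "factin")
  expect_identical(dim(back$voxels), c(38L, 24L, 20L))
  expect_true(all(back$voxels == arr))
})

test_that("reader rejects missing files, ragged series and bit-depth mismatch", {
  cal8 <- calibration(bit_depth = 8)
  expect_error(read_stack(tempfile(), cal8), "no such file")
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(list(matrix(0.5, 8, 8), matrix(0.5, 9, 8)), path,
                  bits.per.sample = 16)
  expect_error(read_stack(path, calibration()), "ragged")
  path2 <- withr::local_tempfile(fileext = ".tif")
  write_stack(make_stack(array(40000, c(2, 4, 4)), calibration()), path2)
  expect_error(read_stack(path2, cal8), "mismatch")
})

test_that("square ROI construction realises the 3,230 um^2 target closely", {
  cal <- calibration()
  roi <- roi_spec_for_area(3230, cal)
  expect_equal(roi$width, roi$height)
  expect_equal(roi$width, round(sqrt(3230) / 0.24))
  expect_lt(abs(roi$physical_area - 3230) / 3230, 0.002)
  expect_error(roi_spec(0, 0, 0, 5, cal), ">= 1")
})

test_that("ROI extraction crops the stated half-open block", {
  cal <- calibration(dx = 1, dy = 1, dz = 1)
  arr <- array(seq_len(2 * 10 * 12), c(2, 10, 12))
  stk <- make_stack(arr, cal)
  full <- roi_spec(0, 0, 12, 10, cal)
  expect_equal(extract_roi(stk, full, 1), arr[2, , ])
  sub <- roi_spec(3, 2, 4, 5, cal)
  blk <- extract_roi(stk, sub, 0)
  expect_equal(dim(blk), c(5, 4))
  expect_equal(blk, arr[1, 3:7, 4:7])
  expect_error(extract_roi(stk, roi_spec(10, 0, 4, 4, cal), 0), "bounds")
})

test_that("volume crops validate bounds and report extents", {
  expect_error(volume_crop(0, 0, 0, 5, 0, 5), "positive extent")
  cr <- volume_crop(0, 38, 0, 246, 10, 246)
  expect_equal(unname(tmquant:::crop_dims(cr)), c(38L, 246L, 236L))
  stk <- make_stack(array(0, c(4, 6, 6)), calibration())
  expect_error(crop_stack(stk, volume_crop(0, 5, 0, 6, 0, 6)), "exceeds")
})

test_that("config files supply calibration with sensible fallbacks", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("voxel_size_um:", "  dx: 0.5", "  dy: 0.5", "  dz: 2",
               "bit_depth: 8", "seed: 7"), path)
  cfg <- read_config(path)
  expect_equal(cfg$calibration$dz, 2)
  expect_equal(cfg$calibration$max_intensity, 255L)
  expect_equal(cfg$seed, 7)
  path2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines("seed: 1", path2)
  expect_equal(read_config(path2)$calibration$dx, 0.24)
})
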