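test_that("ROI mean intensity equals an explicit pixel-loop average", {
  cal <- calibration(dx = 1, dy = 1, dz = 1)
  stk <- make_stack(array(100, c(2, 8, 8)), cal)
  roi <- roi_spec(0, 0, 8, 8, cal)
  expect_equal(roi_mean_intensity(stk, roi, 0), 100)
  half <- array(0, c(1, 10, 10)); half[1, 1:5, ] <- 200
  expect_equal(roi_mean_intensity(make_stack(half, cal),
                                  roi_spec(0, 0, 10, 10, cal), 0), 100)
  set.seed(1)
  arr <- array(round(runif(3 * 12 * 12, 0, 60000)), c(3, 12, 12))
  stk <- make_stack(arr, cal)
  roi <- roi_spec(2, 3, 7, 5, cal)
  s <- 0
  for (yy in 4:8) for (xx in 3:9) s <- s + arr[2, yy, xx]
  expect_equal(roi_mean_intensity(stk, roi, 1), s / 35, tolerance = 1e-12)
})

test_that("uniform signal with equal counts gives the exact ratio and scales linearly", {
  fx <- density_fixture(99)
  # replace red with a constant field, both ROIs with planted nuclei
  fx2 <- density_fixture(101)
  red100 <- make_stack(array(100, dim(fx2$red$voxels)), fx2$cal)
  res <- adjusted_intensity(red100, fx2$green, fx2$rois)
  inc <- res$per_roi[res$per_roi$included, ]
  expect_equal(res$adjusted_intensity, mean(100 / inc$n_nuclei))
  # doubling the red channel doubles the measure (no clipping)
  res1 <- adjusted_intensity(fx$red, fx$green, fx$rois)
  red2 <- make_stack(fx$red$voxels * 2, fx$cal)
  res2 <- adjusted_intensity(red2, fx$green, fx$rois)
  expect_equal(res2$adjusted_intensity, 2 * res1$adjusted_intensity,
               tolerance = 1e-12)
  # permuting ROI order leaves the grand mean unchanged
  res3 <- adjusted_intensity(fx$red, fx$green, rev(fx$rois))
  expect_equal(res3$adjusted_intensity, res1$adjusted_intensity)
})

test_that("ROIs without nuclei are excluded and all-empty input errors", {
  cal <- calibration(dx = 1, dy = 1, dz = 1)
  red <- make_stack(array(50, c(8, 40, 40)), cal)
  green <- array(0, c(8, 40, 40))
  green <- add_disk(green, 1, 10, 10, 2.8, cal, 20000)
  gs <- make_stack(green, cal, "autofluor_nuclei")
  rois <- list(roi_spec(0, 0, 20, 20, cal), roi_spec(20, 0, 20, 20, cal))
  res <- adjusted_intensity(red, gs, rois)
  expect_equal(res$excluded_rois, 2L)
  expect_equal(res$adjusted_intensity, 50)
  empty <- make_stack(array(0, c(8, 40, 40)), cal, "autofluor_nuclei")
  expect_error(adjusted_intensity(red, empty, rois), "zero nuclear count")
})

test_that("autofluorescence ROI intensity matches a loop oracle and the configured beam scale", {
  cal <- calibration(dx = 1, dy = 1, dz = 1)
  set.seed(8)
  arr <- array(round(runif(8 * 30 * 30, 0, 8000)), c(8, 30, 30))
  g <- make_stack(arr, cal, "autofluor_nuclei")
  rois <- list(roi_spec(0, 0, 12, 12, cal), roi_spec(15, 15, 12, 12, cal))
  res <- autofluorescence_intensity(g, rois, stride_um = 2)
  oracle <- mean(vapply(rois, function(roi) {
    ms <- c()
    for (z in seq(0, 7, 2)) {
      s <- 0
      for (yy in seq(roi$y0 + 1, roi$y0 + 12))
        for (xx in seq(roi$x0 + 1, roi$x0 + 12)) s <- s + arr[z + 1, yy, xx]
      ms <- c(ms, s / 144)
    }
    mean(ms)
  }, numeric(1)))
  expect_equal(res$mean_af_intensity, oracle, tolerance = 1e-12)
  expect_equal(autofluorescence_intensity(
    make_stack(array(4000, c(4, 10, 10)), cal, "autofluor_nuclei"),
    list(roi_spec(0, 0, 10, 10, cal)))$mean_af_intensity, 4000)
  # generator default beam autofluorescence sits at the thousands scale
  pr <- generate_tissue_pair(small_params(seed = 6L, noise = FALSE))
  beam_mean <- mean(pr$control$green$voxels[pr$control$truth$beam_mask])
  expect_gt(beam_mean, 3000); expect_lt(beam_mean, 5000)
})
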