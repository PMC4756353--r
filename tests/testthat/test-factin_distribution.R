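test_that("the intensity window is strict at both boundaries", {
  cal <- calibration()
  arr <- array(0, c(1, 1, 4))
  arr[1, 1, ] <- c(10025, 10026, 65519, 0)
  map <- segment_factin_3d(arr, cal = cal)
  expect_equal(sum(map$labels > 0), 2)  # 10025 out, 10026 and 65519 in
  expect_equal(segment_factin_3d(array(10025, c(2, 2, 2)),
                                 cal = cal)$total_volume_um3, 0)
  expect_error(segment_factin_3d(arr, window = c(5, 5), cal = cal), "lo < hi")
  expect_match(paste(map$notes, collapse = " "), "65540")
})

test_that("a solid supra-threshold cuboid measures its exact physical volume", {
  cal <- calibration()
  arr <- array(0, c(14, 14, 14))
  arr[3:12, 3:12, 3:12] <- 30000
  map <- segment_factin_3d(arr, cal = cal)
  expect_equal(nrow(map$components), 1)
  expect_equal(map$components$n_voxels, 1000L)
  expect_equal(map$total_volume_um3, 57.6)
  expect_equal(segment_factin_3d(array(0, c(4, 4, 4)),
                                 cal = cal)$total_volume_um3, 0)
})

test_that("map volume is invariant to relabelling, transposition, and grows as the window relaxes", {
  cal <- calibration(dx = 0.5, dy = 0.5, dz = 0.5)
  set.seed(12)
  arr <- array(round(runif(10 * 12 * 14, 0, 30000)), c(10, 12, 14))
  m1 <- segment_factin_3d(arr, window = c(15000, 65540), cal = cal)
  m2 <- segment_factin_3d(aperm(arr, c(3, 2, 1)), window = c(15000, 65540),
                          cal = cal)
  expect_equal(m1$total_volume_um3, m2$total_volume_um3)
  m3 <- segment_factin_3d(arr, window = c(10000, 65540), cal = cal)
  expect_gte(m3$total_volume_um3, m1$total_volume_um3)
  # minimum feature size drops only small components
  m4 <- segment_factin_3d(arr, window = c(15000, 65540), cal = cal,
                          min_feature_um3 = 1)
  expect_true(all(m4$components$volume_um3 >= 1))
  expect_lte(m4$total_volume_um3, m1$total_volume_um3)
})

test_that("the 3 x 3 partition tiles the crop disjointly with near-equal extents", {
  crop <- volume_crop(0, 38, 0, 1025, 0, 1025)
  tiles <- partition_subvolumes(crop)
  expect_length(tiles, 9)
  w <- vapply(tiles, function(tl) tl$x1 - tl$x0, integer(1))
  h <- vapply(tiles, function(tl) tl$y1 - tl$y0, integer(1))
  expect_lte(diff(range(w)), 1L)   # within one voxel of equal
  expect_lte(diff(range(h)), 1L)
  expect_equal(sum(w[1:3]), 1025L)
  # disjoint cover: every voxel claimed exactly once
  cover <- matrix(0L, 1025, 1025)
  for (tl in tiles)
    cover[(tl$y0 + 1):tl$y1, (tl$x0 + 1):tl$x1] <-
      cover[(tl$y0 + 1):tl$y1, (tl$x0 + 1):tl$x1] + 1L
  expect_true(all(cover == 1L))
  expect_error(partition_subvolumes(volume_crop(0, 1, 0, 2, 0, 2)), "grid")
})

test_that("per-subvolume map volumes add up to the total", {
  cal <- calibration()
  set.seed(33)
  arr <- array(round(runif(12 * 60 * 60, 0, 20000)), c(12, 60, 60))
  map <- segment_factin_3d(arr, window = c(10025, 65540), cal = cal)
  crop <- volume_crop(0, 12, 0, 60, 0, 60)
  tiles <- partition_subvolumes(crop)
  per <- vapply(tiles, function(tl) map_volume_in(map, tl), numeric(1))
  expect_equal(sum(per), map$total_volume_um3, tolerance = 1e-12)
})

test_that("distribution-to-nuclear ratios average as stated and flag empty subvolumes", {
  cal <- calibration()
  arr <- array(0, c(38, 90, 90))
  arr[3:12, 3:12, 3:12] <- 30000   # 57.6 um^3 in tile 1
  map <- segment_factin_3d(arr, cal = cal)
  tiles <- partition_subvolumes(volume_crop(0, 38, 0, 90, 0, 90))
  res <- adjusted_distribution(map, tiles, c(2, rep(1, 8)))
  expect_equal(res$per_subvolume$ratio[1], 28.8)
  expect_equal(res$adjusted_distribution, 28.8 / 9)
  res2 <- adjusted_distribution(map, tiles, c(2, 0, rep(1, 7)))
  expect_equal(res2$excluded_subvolumes, 2L)
  expect_error(adjusted_distribution(map, tiles, rep(0, 9)), "zero nuclear")
})

test_that("thresholded 3D distribution amplifies the programmed actin loss", {
  for (s in 1:6) {
    p <- synth_params(seed = s, actin_effect = 0.3)
    pr <- generate_tissue_pair(p)
    rois <- place_rois(p$ny, p$nx, 5, cal = p$cal)
    dc <- adjusted_intensity(pr$control$red, pr$control$green, rois)
    dt <- adjusted_intensity(pr$treated$red, pr$treated$green, rois)
    int_red <- 100 * (1 - dt$adjusted_intensity / dc$adjusted_intensity)
    rc <- distribution_pipeline(pr$control$red, pr$control$green)
    rt <- distribution_pipeline(pr$treated$red, pr$treated$green)
    dist_red <- 100 * (1 - rt$adjusted_distribution / rc$adjusted_distribution)
    expect_gte(dist_red, int_red)
  }
})
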