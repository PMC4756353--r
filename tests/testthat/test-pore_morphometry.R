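test_that("elliptical area follows the closed form and a raster oracle", {
  expect_equal(ellipse_area(10, 10), pi * 25)
  expect_equal(round(ellipse_area(10, 10), 2), 78.54)
  expect_equal(round(ellipse_area(10, 20), 2), 157.08)
  expect_error(ellipse_area(0, 5), "positive")
  # rasterised ellipse pixel count agrees within 2% for axes >= 10 voxels
  for (ax in list(c(12, 30), c(20, 20), c(15, 44))) {
    a <- ax[1] / 2; b <- ax[2] / 2
    xs <- seq(-ceiling(b), ceiling(b)) # unit pixels
    ys <- seq(-ceiling(a), ceiling(a))
    cnt <- sum(outer(ys^2 / a^2, xs^2 / b^2, "+") <= 1)
    expect_lt(abs(cnt - ellipse_area(ax[1], ax[2])) / cnt, 0.02)
  }
})

test_that("2D pore measurement finds interior voids and rejects clipped ones", {
  cal <- calibration()
  ny <- nx <- 300
  arr <- array(8000, c(1, ny, nx))
  stk0 <- make_stack(arr, cal, "autofluor_nuclei")
  expect_equal(nrow(measure_pores_2d(stk0, 0, grain_um = 0)), 0)
  # one interior elliptical void, axes (20, 40) um
  yc <- ((1:ny) - 0.5) * cal$dy; xc <- ((1:nx) - 0.5) * cal$dx
  hole <- outer((yc - 36)^2 / 10^2, (xc - 36)^2 / 20^2, "+") <= 1
  arr2 <- arr; arr2[1, , ][hole] <- 100
  det <- measure_pores_2d(make_stack(arr2, cal, "autofluor_nuclei"), 0,
                          grain_um = 0)
  expect_equal(nrow(det), 1)
  expect_lt(abs(det$area_um2 - 628.3) / 628.3, 0.05)
  expect_lt(abs(det$long_um - 40) / 40, 0.05)
  # the same void clipped by the frame edge is excluded...
  arr3 <- arr
  hole3 <- outer((yc - 2)^2 / 10^2, (xc - 36)^2 / 20^2, "+") <= 1
  arr3[1, , ][hole3] <- 100
  stk3 <- make_stack(arr3, cal, "autofluor_nuclei")
  expect_equal(nrow(measure_pores_2d(stk3, 0, grain_um = 0)), 0)
  # ...but reported with a flag on request
  kept <- measure_pores_2d(stk3, 0, grain_um = 0, keep_border = TRUE)
  expect_true(all(kept$border_touching))
})

test_that("AF foreground and voids tile the crop exactly when filters are off", {
  cal <- calibration()
  off_af <- list(grain_um = 0, cutoff = 3600, min_volume_um3 = 0)
  off_void <- list(grain_um = 0, cutoff = "auto", min_volume_um3 = 0)
  for (s in 1:5) {
    set.seed(s)
    arr <- array(sample(c(0, 8000), 8 * 20 * 20, replace = TRUE),
                 c(8, 20, 20))
    res <- void_volume_3d(make_stack(arr, cal, "autofluor_nuclei"),
                          af_params = off_af, void_params = off_void)
    expect_equal(res$af_volume_um3 + res$total_void_volume_um3,
                 res$crop_volume_um3)
    expect_true(all(!(res$af_mask & res$void_mask)))
  }
})

test_that("a spherical void recovers its analytic volume", {
  cal <- calibration(dx = 0.24, dy = 0.24, dz = 0.24)
  n <- 50L
  arr <- array(8000, c(n, n, n))
  cc <- (n / 2) * 0.24
  zc <- ((1:n) - 0.5) * 0.24
  for (z in 1:n) {
    d2 <- outer((zc[z] - cc)^2 + (zc - cc)^2, (zc - cc)^2, "+")
    arr[z, , ][d2 <= 25] <- 0
  }
  res <- void_volume_3d(make_stack(arr, cal, "autofluor_nuclei"),
                        af_params = list(grain_um = 0, cutoff = 3600,
                                         min_volume_um3 = 0),
                        void_params = list(grain_um = 0, cutoff = "auto",
                                           min_volume_um3 = 0))
  expect_equal(nrow(res$voids), 1)
  v_true <- 4 / 3 * pi * 125
  expect_lt(abs(res$total_void_volume_um3 - v_true) / v_true, 0.03)
})

test_that("dilating pores increases measured 2D area and 3D void volume", {
  for (s in 1:4) {
    base <- generate_tissue_pair(small_params(seed = s, pore_dilation_um = 0))
    dil <- generate_tissue_pair(small_params(seed = s, pore_dilation_um = 1.5))
    a0 <- measure_pores_2d(base$treated$green, 19)
    a1 <- measure_pores_2d(dil$treated$green, 19)
    if (nrow(a0) && nrow(a1))
      expect_gt(mean(a1$area_um2), mean(a0$area_um2))
    v0 <- void_volume_3d(base$treated$green)
    v1 <- void_volume_3d(dil$treated$green)
    expect_gt(v1$total_void_volume_um3, v0$total_void_volume_um3)
  }
})

test_that("pore summaries reproduce the printed group-mean percent changes", {
  # worked example on published group means: areas 813.6 -> 1,103.4 um^2
  # and volumes 166,297.3 -> 274,042.8 um^3
  s <- pore_summary(list(areas_um2 = 813.6, volumes_um3 = 166297.3),
                    list(areas_um2 = 1103.4, volumes_um3 = 274042.8))
  expect_equal(s$table$pct_change_rounded,
               c(36, 65))
  ident <- pore_summary(list(areas_um2 = c(100, 200)),
                        list(areas_um2 = c(100, 200)))
  expect_equal(ident$table$pct_change, 0)
  expect_error(pore_summary(list(), list(areas_um2 = 1)), "empty")
})
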