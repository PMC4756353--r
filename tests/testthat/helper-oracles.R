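# Naive, loop-based re-implementation of the nuclei-normalised ROI density
# (no code shared with the package): per ROI, the mean grey value over the
# sampled sections by explicit pixel loops, divided by the known nuclear
# count; grand mean over ROIs with positive counts.
naive_adjusted_intensity <- function(red_arr, rois, sections, counts) {
  ratios <- c()
  for (i in seq_along(rois)) {
    roi <- rois[[i]]
    sec_means <- c()
    for (z in sections) {
      s <- 0; px <- 0
      for (yy in seq(roi$y0 + 1, roi$y0 + roi$height))
        for (xx in seq(roi$x0 + 1, roi$x0 + roi$width)) {
          s <- s + red_arr[z + 1, yy, xx]
          px <- px + 1
        }
      sec_means <- c(sec_means, s / px)
    }
    if (counts[i] > 0)
      ratios <- c(ratios, mean(sec_means) / counts[i])
  }
  mean(ratios)
}

# random paired-fixture builder for the Eq.-style density check: red stack
# is uniform noise; green stack carries `counts[i]` bright disks inside ROI
# i of section 0 so the package's detector recovers the planted counts.
density_fixture <- function(seed) {
  set.seed(seed)
  cal <- calibration(dx = 1, dy = 1, dz = 1)
  nz <- 8L; ny <- 40L; nx <- 80L
  red <- array(runif(nz * ny * nx, 0, 5000), c(nz, ny, nx))
  green <- array(0, c(nz, ny, nx))
  rois <- list(roi_spec(0, 0, 36, 36, cal), roi_spec(40, 0, 36, 36, cal))
  counts <- c(sample(0:3, 1), sample(1:3, 1))  # at least one ROI included
  slots <- list(c(9, 9), c(9, 27), c(27, 9), c(27, 27))  # (y, x) um in ROI
  for (i in seq_along(rois)) {
    if (counts[i] == 0) next
    for (k in seq_len(counts[i]))
      green <- add_disk(green, 1, slots[[k]][1],
                        rois[[i]]$x0 + slots[[k]][2], 2.8, cal, 20000)
  }
  list(red = make_stack(round(red), cal, "factin"),
       green = make_stack(green, cal, "autofluor_nuclei"),
       rois = rois, counts = counts, cal = cal)
}

# independent formula-level oracle for the paired log t statistic
hand_paired_log_t <- function(control, treated) {
  d <- log(control) - log(treated)
  n <- length(d)
  m <- sum(d) / n
  s2 <- sum((d - m)^2) / (n - 1)
  m / sqrt(s2 / n)
}

# independent pooled two-proportion z oracle
hand_pooled_z <- function(x1, n1, x2, n2) {
  p1 <- x1 / n1; p2 <- x2 / n2; ph <- (x1 + x2) / (n1 + n2)
  (p1 - p2) / sqrt(ph * (1 - ph) * (1 / n1 + 1 / n2))
}
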