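#' Count live and dead cells and compute percent viability
#'
#' Counts calcein-positive (live) and PI-positive (dead) cells through the
#' full z-stack using the 3D blob detector with channel-appropriate volume
#' gates. A blob detected in both channels (possible in noisy data) is
#' assigned to the dead class — PI labelling of a compromised nucleus
#' overrides cytosolic calcein signal — and the reassignment is reported.
#' Viability is the percentage of live cells among all cells; specimens
#' below 50% viability are flagged excluded by the conventional quality
#' rule.
#'
#' @param calcein,pi [channel_stack()]s of the calcein and propidium-iodide
#'   channels (identical dimensions).
#' @param live_min_volume_um3,dead_min_volume_um3 Minimum component volumes
#'   for the two channels (live cells are whole-cell cytosolic blobs, dead
#'   signals are nuclear and smaller).
#' @param coincidence_dist_um Maximum centroid distance at which a live and
#'   a dead detection are considered the same cell.
#' @param min_threshold Passed to [detect_blobs_3d()].
#' @return An object of class `"viability_result"`: `n_live`, `n_dead`,
#'   `n_total`, `percent_live`, `percent_dead`
#'   (`percent_live + percent_dead == 100`), `n_dual_positive`, `excluded`
#'   (viability below 50%).
#' @export
count_live_dead <- function(calcein, pi,
                            live_min_volume_um3 = 100,
                            dead_min_volume_um3 = 30,
                            coincidence_dist_um = 4,
                            min_threshold = 2000) {
  stopifnot(is_channel_stack(calcein), is_channel_stack(pi))
  if (!identical(dim(calcein$voxels), dim(pi$voxels)))
    stop("calcein and PI stacks must have identical dimensions")
  cal <- calcein$calibration
  live <- detect_blobs_3d(calcein, min_volume_um3 = live_min_volume_um3,
                          min_threshold = min_threshold)
  dead <- detect_blobs_3d(pi, min_volume_um3 = dead_min_volume_um3,
                          min_threshold = min_threshold)
  n_dual <- 0L
  if (nrow(live) && nrow(dead)) {
    lc <- cbind(live$x * cal$dx, live$y * cal$dy, live$z * cal$dz)
    dc <- cbind(dead$x * cal$dx, dead$y * cal$dy, dead$z * cal$dz)
    dual <- vapply(seq_len(nrow(lc)), function(i)
      min(sqrt(rowSums(sweep(dc, 2, lc[i, ])^2))) <= coincidence_dist_um,
      logical(1))
    n_dual <- sum(dual)
    live <- live[!dual, , drop = FALSE]
  }
  n_live <- nrow(live); n_dead <- nrow(dead)
  n_total <- n_live + n_dead
  if (n_total == 0)
    stop("no cells detected in either channel; percent viability undefined")
  pl <- 100 * n_live / n_total
  structure(list(n_live = n_live, n_dead = n_dead, n_total = n_total,
                 percent_live = pl, percent_dead = 100 - pl,
                 n_dual_positive = n_dual, excluded = pl < 50),
            class = "viability_result")
}

#' @export
print.viability_result <- function(x, ...) {
  cat(sprintf("<viability_result> %d live / %d dead (%0.1f%% live)%s\n",
              x$n_live, x$n_dead, x$percent_live,
              if (x$excluded) " [excluded: viability < 50%]" else ""))
  invisible(x)
}

#' Two-proportion z-test (pooled)
#'
#' Tests equality of two binomial proportions with the pooled-variance
#' z statistic
#' `z = (p1 - p2) / sqrt(phat (1 - phat) (1/n1 + 1/n2))`,
#' `phat` the pooled proportion; two-sided p from the standard normal.
#' `z^2` equals the 2 x 2 chi-square statistic without continuity
#' correction.
#'
#' @param live1,total1 Successes and trials in group 1 (`0 <= live1 <=
#'   total1`, `total1 > 0`).
#' @param live2,total2 As above for group 2.
#' @return A list with `z`, `p_value`, `p1`, `p2`, `pooled`.
#' @export
two_proportion_ztest <- function(live1, total1, live2, total2) {
  if (total1 <= 0 || total2 <= 0) stop("group totals must be positive")
  if (live1 < 0 || live2 < 0 || live1 > total1 || live2 > total2)
    stop("counts must satisfy 0 <= live <= total")
  p1 <- live1 / total1; p2 <- live2 / total2
  ph <- (live1 + live2) / (total1 + total2)
  se <- sqrt(ph * (1 - ph) * (1 / total1 + 1 / total2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)),
       p1 = p1, p2 = p2, pooled = ph)
}
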