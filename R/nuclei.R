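#' Detect nuclei in one optical section
#'
#' Segments blob-like nuclear footprints in the green
#' (autofluorescence + Hoechst) channel of a single section: automatic
#' (Otsu) intensity thresholding with a configurable floor, hole filling,
#' 8-connected component labelling, then a size and shape gate that keeps
#' compact elliptical footprints and rejects fibrous autofluorescent
#' structure (beams are large and/or ramified, so they fail the area,
#' solidity or eccentricity criteria).
#'
#' @param stack A [channel_stack()] (green channel).
#' @param z 0-based section index.
#' @param min_area_um2,max_area_um2 Plausible nuclear footprint area range.
#' @param min_solidity Minimum footprint solidity (area / convex area).
#' @param max_eccentricity Maximum moment-ellipse eccentricity.
#' @param min_threshold Intensity floor applied to the automatic threshold,
#'   guarding against Otsu bisecting pure background noise.
#' @return A data.frame with one row per detection: `z` (section), `y`, `x`
#'   (0-based continuous centroid, voxels), `area_um2`, `n_pixels`,
#'   `solidity`, `eccentricity`. Zero rows when nothing is detected.
#' @export
detect_nuclei_section <- function(stack, z,
                                  min_area_um2 = 20, max_area_um2 = 200,
                                  min_solidity = 0.8,
                                  max_eccentricity = 0.95,
                                  min_threshold = 2000) {
  stopifnot(is_channel_stack(stack))
  cal <- stack$calibration
  d <- dim(stack$voxels)
  if (z < 0 || z >= d[1]) stop("section index out of range: ", z)
  sec <- stack$voxels[z + 1L, , ]
  empty <- data.frame(z = integer(0), y = numeric(0), x = numeric(0),
                      area_um2 = numeric(0), n_pixels = integer(0),
                      solidity = numeric(0), eccentricity = numeric(0))
  mx <- cal$max_intensity
  thr <- tryCatch(
    EBImage::otsu(sec / mx, range = c(0, 1), levels = mx + 1L) * mx,
    error = function(e) Inf)
  thr <- max(thr, min_threshold)
  mask <- sec > thr
  if (!any(mask)) return(empty)
  mask <- as.logical(EBImage::fillHull(mask))
  dim(mask) <- dim(sec)
  labels <- label_components_3d(mask)
  k <- attr(labels, "n_components")
  if (k == 0) return(empty)
  lab2d <- labels[1, , ]
  px_area <- cal$dx * cal$dy
  out <- vector("list", k)
  for (lb in seq_len(k)) {
    ij <- which(lab2d == lb, arr.ind = TRUE)  # (row=y, col=x) 1-based
    n_pix <- nrow(ij)
    area <- n_pix * px_area
    if (area < min_area_um2 || area > max_area_um2) next
    xy <- cbind(x = ij[, 2] - 1, y = ij[, 1] - 1)
    sol <- .pixel_solidity(xy)
    ecc <- .pixel_eccentricity(xy)
    if (sol < min_solidity || ecc > max_eccentricity) next
    out[[lb]] <- data.frame(z = z, y = mean(xy[, "y"]), x = mean(xy[, "x"]),
                            area_um2 = area, n_pixels = n_pix,
                            solidity = sol, eccentricity = ecc)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

# solidity = pixel count / lattice-point area of the convex hull
# (hull lattice area by Pick's theorem: interior + boundary = A + B/2 + 1)
.pixel_solidity <- function(xy) {
  n <- nrow(xy)
  if (n <= 3) return(1)
  h <- grDevices::chull(xy)
  hx <- xy[h, 1]; hy <- xy[h, 2]
  m <- length(h)
  if (m < 3) return(1)
  j <- c(2:m, 1)
  A <- abs(sum(hx * hy[j] - hx[j] * hy)) / 2
  B <- sum(mapply(function(dx, dy) .gcd(abs(dx), abs(dy)),
                  hx[j] - hx, hy[j] - hy))
  hull_pts <- A + B / 2 + 1
  min(1, n / hull_pts)
}

.gcd <- function(a, b) { while (b) { t <- b; b <- a %% b; a <- t }; max(a, 1) }

.pixel_eccentricity <- function(xy) {
  if (nrow(xy) < 3) return(0)
  cv <- stats::cov(xy) + diag(1 / 12, 2)  # pixel extent correction
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  sqrt(max(0, 1 - ev[2] / ev[1]))
}

.stride_step <- function(z_stride_um, cal) {
  if (z_stride_um < cal$dz)
    stop("z stride (", z_stride_um, " um) must be >= section spacing dz (",
         cal$dz, " um)")
  max(1L, as.integer(round(z_stride_um / cal$dz)))
}

#' Count nuclei inside an ROI over interval-sampled sections
#'
#' Sections are sampled every `round(z_stride_um / dz)` frames starting at
#' `z_start`; a detection belongs to the ROI if its centroid voxel falls
#' inside the ROI rectangle (centroid membership avoids double counting at
#' ROI borders). The stride (conventionally 8 um) is chosen so nuclei are
#' neither double-counted across sampled sections nor missed between them.
#'
#' @inheritParams detect_nuclei_section
#' @param roi A [roi_spec()].
#' @param z_stride_um Sampling interval in micrometres (default 8).
#' @param z_start First sampled section (0-based; default 0).
#' @param ... Passed to [detect_nuclei_section()].
#' @return Integer count.
#' @export
count_nuclei_roi <- function(stack, roi, z_stride_um = 8, z_start = 0L, ...) {
  cal <- stack$calibration
  step <- .stride_step(z_stride_um, cal)
  nz <- dim(stack$voxels)[1]
  sections <- seq(z_start, nz - 1L, by = step)
  n <- 0L
  for (z in sections) {
    det <- detect_nuclei_section(stack, z, ...)
    if (!nrow(det)) next
    xi <- round(det$x); yi <- round(det$y)
    n <- n + sum(xi >= roi$x0 & xi < roi$x0 + roi$width &
                 yi >= roi$y0 & yi < roi$y0 + roi$height)
  }
  n
}

#' Count nuclei inside a 3D subvolume over interval-sampled sections
#'
#' As [count_nuclei_roi()], with membership decided by the subvolume's x/y
#' bounds and sampling restricted to its z range (starting at its first
#' section).
#'
#' @inheritParams count_nuclei_roi
#' @param crop A [volume_crop()].
#' @return Integer count.
#' @export
count_nuclei_subvolume <- function(stack, crop, z_stride_um = 8, ...) {
  stopifnot(inherits(crop, "volume_crop"))
  cal <- stack$calibration
  check_crop_within(crop, dim(stack$voxels))
  step <- .stride_step(z_stride_um, cal)
  sections <- seq(crop$z0, crop$z1 - 1L, by = step)
  n <- 0L
  for (z in sections) {
    det <- detect_nuclei_section(stack, z, ...)
    if (!nrow(det)) next
    xi <- round(det$x); yi <- round(det$y)
    n <- n + sum(xi >= crop$x0 & xi < crop$x1 &
                 yi >= crop$y0 & yi < crop$y1)
  }
  n
}

#' Detect bright blobs in 3D through the whole stack
#'
#' The 3D analogue of the section detector, used for live/dead cell
#' counting: global automatic thresholding (with a floor), 26-connected
#' component labelling, and a physical-volume gate.
#'
#' @inheritParams detect_nuclei_section
#' @param min_volume_um3,max_volume_um3 Component volume gate.
#' @return A data.frame with `z`, `y`, `x` (0-based continuous centroid)
#'   and `volume_um3` per retained component.
#' @export
detect_blobs_3d <- function(stack, min_volume_um3 = 30,
                            max_volume_um3 = Inf, min_threshold = 2000) {
  stopifnot(is_channel_stack(stack))
  cal <- stack$calibration
  mx <- cal$max_intensity
  v <- stack$voxels
  thr <- tryCatch(
    EBImage::otsu(matrix(v, nrow = dim(v)[2]) / mx,
                  range = c(0, 1), levels = mx + 1L) * mx,
    error = function(e) Inf)
  thr <- max(thr, min_threshold)
  mask <- v > thr
  labels <- label_components_3d(mask)
  k <- attr(labels, "n_components")
  empty <- data.frame(z = numeric(0), y = numeric(0), x = numeric(0),
                      volume_um3 = numeric(0))
  if (k == 0) return(empty)
  vv <- voxel_volume(cal)
  idx <- which(labels > 0L)
  lb <- labels[idx]
  ai <- arrayInd(idx, dim(labels))
  counts <- tabulate(lb, nbins = k)
  keep <- which(counts * vv >= min_volume_um3 & counts * vv <= max_volume_um3)
  if (!length(keep)) return(empty)
  rows <- lapply(keep, function(l) {
    sel <- lb == l
    data.frame(z = mean(ai[sel, 1] - 1), y = mean(ai[sel, 2] - 1),
               x = mean(ai[sel, 3] - 1), volume_um3 = counts[l] * vv)
  })
  do.call(rbind, rows)
}

#' Export a detection table
#' @param detections A data.frame from [detect_nuclei_section()] or
#'   [detect_blobs_3d()].
#' @param path Output CSV path.
#' @export
write_detections <- function(detections, path) {
  utils::write.csv(detections, path, row.names = FALSE)
  invisible(path)
}
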