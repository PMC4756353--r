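#' Label connected components in a 3D binary mask
#'
#' Thin wrapper over the compiled flood-fill labeller. Components are
#' labelled 1..K in raster-scan order; background voxels get 0.
#'
#' @param mask Logical 3D array, dims `(nz, ny, nx)` (a matrix is treated as
#'   a single-section stack).
#' @param connectivity 26 (default; faces, edges and corners) or 6 (faces).
#' @return Integer array of labels, same dims as `mask`, with attribute
#'   `n_components`.
#' @export
label_components_3d <- function(mask, connectivity = 26L) {
  if (is.matrix(mask)) dim(mask) <- c(1L, dim(mask))
  stopifnot(length(dim(mask)) == 3L)
  .cc_label_3d(as.logical(mask), as.integer(dim(mask)),
               as.integer(connectivity))
}

#' Separable 3D Gaussian smoothing
#'
#' Convolves a stack with an axis-separable Gaussian kernel (reflective
#' boundary handling). Axes whose standard deviation is below 0.3 voxels are
#' left untouched, since the kernel would be indistinguishable from a delta.
#'
#' @param arr Numeric 3D array, dims `(nz, ny, nx)`.
#' @param sd_um Gaussian standard deviation in micrometres (scalar).
#' @param cal A [calibration()] converting `sd_um` to per-axis voxel SDs.
#' @return Smoothed numeric array, same dims.
#' @export
gaussian_blur_3d <- function(arr, sd_um, cal) {
  stopifnot(length(dim(arr)) == 3L, sd_um >= 0)
  if (sd_um == 0) return(arr)
  sds <- sd_um / c(cal$dz, cal$dy, cal$dx)  # per axis (z, y, x)
  for (ax in 1:3) {
    if (sds[ax] < 0.3) next
    arr <- .blur_axis(arr, ax, sds[ax])
  }
  arr
}

# Convolve along one axis with reflective padding, via stats::filter on a
# (axis, rest) matrix layout.
.blur_axis <- function(arr, axis, sd_vox) {
  r <- max(1L, as.integer(ceiling(3 * sd_vox)))
  k <- stats::dnorm(seq(-r, r), sd = sd_vox)
  k <- k / sum(k)
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = d[axis])
  n <- nrow(m)
  pad_top <- m[pmin(n, (r + 1L):2L), , drop = FALSE]     # reflect
  pad_bot <- m[pmax(1L, (n - 1L):(n - r)), , drop = FALSE]
  padded <- rbind(pad_top, m, pad_bot)
  f <- stats::filter(padded, k, method = "convolution", sides = 2)
  out <- f[(r + 1L):(r + n), , drop = FALSE]
  a <- array(out, dim = d[perm])
  aperm(a, order(perm))
}

#' Segment supra-threshold F-actin voxels in 3D
#'
#' Builds the voxel analogue of an isosurface map: voxels whose intensity
#' lies strictly inside the window `(lo, hi)` are grouped into 26-connected
#' components, optionally after Gaussian pre-smoothing, and components below
#' a minimum physical volume are dropped. The measured quantity is the total
#' physical volume of the retained components.
#'
#' @param stack A [channel_stack()] (red / F-actin channel) or 3D array.
#' @param window Length-2 numeric `(lo, hi)`; voxels with `lo < I < hi` are
#'   foreground. The conventional F-actin window is `(10025, 65540)`; the
#'   upper bound exceeds the 16-bit maximum 65535 and therefore imposes no
#'   cut, which is honoured as stated (a note is attached to the result).
#' @param min_feature_um3 Minimum component volume retained, in um^3
#'   (default 0: the native voxel size is the only size criterion).
#' @param grain_um Smoothing grain; Gaussian SD is `grain_um / 2` (0 = off).
#' @param cal A [calibration()]; defaults to the stack's own.
#' @param connectivity Passed to [label_components_3d()].
#' @return An object of class `"segmentation_map"`: list with `labels`
#'   (integer array), `components` (data.frame: label, n_voxels,
#'   volume_um3), `total_volume_um3`, `window`, `min_feature_um3`,
#'   `grain_um`, `notes`.
#' @export
segment_factin_3d <- function(stack, window = c(10025, 65540),
                              min_feature_um3 = 0, grain_um = 0,
                              cal = NULL, connectivity = 26L) {
  if (is_channel_stack(stack)) {
    if (is.null(cal)) cal <- stack$calibration
    arr <- stack$voxels
  } else {
    if (is.null(cal)) stop("cal required when stack is a bare array")
    arr <- stack
  }
  if (length(window) != 2L || window[1] >= window[2])
    stop("window must be (lo, hi) with lo < hi")
  notes <- character(0)
  if (window[2] > cal$max_intensity)
    notes <- c(notes, sprintf(
      "upper window bound %s exceeds the %d-bit maximum %d; no upper cut applies",
      format(window[2]), cal$bit_depth, cal$max_intensity))
  if (grain_um > 0) arr <- gaussian_blur_3d(arr, grain_um / 2, cal)
  mask <- arr > window[1] & arr < window[2]
  labels <- label_components_3d(mask, connectivity)
  k <- attr(labels, "n_components")
  vv <- voxel_volume(cal)
  if (k > 0) {
    counts <- tabulate(labels[labels > 0L], nbins = k)
    comp <- data.frame(label = seq_len(k), n_voxels = counts,
                       volume_um3 = counts * vv)
    if (min_feature_um3 > 0) {
      drop <- comp$label[comp$volume_um3 < min_feature_um3]
      if (length(drop)) {
        labels[labels %in% drop] <- 0L
        comp <- comp[!comp$label %in% drop, , drop = FALSE]
      }
    }
  } else {
    comp <- data.frame(label = integer(0), n_voxels = integer(0),
                       volume_um3 = numeric(0))
  }
  structure(list(labels = labels, components = comp,
                 total_volume_um3 = sum(comp$volume_um3),
                 window = window, min_feature_um3 = min_feature_um3,
                 grain_um = grain_um, calibration = cal, notes = notes),
            class = "segmentation_map")
}

#' @export
print.segmentation_map <- function(x, ...) {
  cat(sprintf("<segmentation_map> %d components, total %.4g um^3, window (%s, %s)\n",
              nrow(x$components), x$total_volume_um3,
              format(x$window[1]), format(x$window[2])))
  for (n in x$notes) cat("  note: ", n, "\n", sep = "")
  invisible(x)
}

#' Export a segmentation map as a labelled TIFF and component table
#'
#' @param map A `segmentation_map`.
#' @param tiff_path,csv_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the component data.frame.
#' @export
write_segmentation_map <- function(map, tiff_path = NULL, csv_path = NULL) {
  if (!is.null(tiff_path)) {
    lab <- map$labels
    mx <- max(1L, max(lab))
    pages <- lapply(seq_len(dim(lab)[1]), function(z) lab[z, , ] / mx)
    tiff::writeTIFF(pages, tiff_path, bits.per.sample = 16)
  }
  if (!is.null(csv_path))
    utils::write.csv(map$components, csv_path, row.names = FALSE)
  invisible(map$components)
}
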