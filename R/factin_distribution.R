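#' Partition an analysis crop into a 3 x 3 grid of subvolumes
#'
#' Splits the crop's x and y extents into near-equal thirds (within one
#' voxel when the extent is not divisible by 3; leading tiles take the
#' extra voxel), each tile keeping the full z depth. A 246 x 246 x 38 um
#' crop yields nine 82 x 82 x 38 um subvolumes.
#'
#' @param crop A [volume_crop()].
#' @param grid Integer 2-vector `(rows, cols)`; default `c(3, 3)`.
#' @return A list of `rows * cols` [volume_crop()]s, disjoint with union
#'   equal to `crop`, in row-major (y-then-x) order.
#' @export
partition_subvolumes <- function(crop, grid = c(3L, 3L)) {
  stopifnot(inherits(crop, "volume_crop"), length(grid) == 2)
  d <- crop_dims(crop)
  if (d[2] < grid[1] || d[3] < grid[2])
    stop("crop smaller than the requested grid")
  cuts <- function(lo, hi, k) {
    n <- hi - lo
    sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
    b <- lo + cumsum(c(0L, sizes))
    cbind(b[-length(b)], b[-1])
  }
  yb <- cuts(crop$y0, crop$y1, grid[1])
  xb <- cuts(crop$x0, crop$x1, grid[2])
  out <- vector("list", grid[1] * grid[2])
  k <- 0L
  for (iy in seq_len(grid[1])) for (ix in seq_len(grid[2])) {
    k <- k + 1L
    out[[k]] <- volume_crop(crop$z0, crop$z1,
                            yb[iy, 1], yb[iy, 2], xb[ix, 1], xb[ix, 2])
  }
  out
}

#' Segmented (map) volume inside a subvolume
#'
#' @param map A `segmentation_map` (see [segment_factin_3d()]).
#' @param crop A [volume_crop()] in the map's voxel grid.
#' @return Physical volume (um^3) of map foreground inside the crop.
#' @export
map_volume_in <- function(map, crop) {
  check_crop_within(crop, dim(map$labels))
  sub <- map$labels[(crop$z0 + 1L):crop$z1,
                    (crop$y0 + 1L):crop$y1,
                    (crop$x0 + 1L):crop$x1]
  sum(sub > 0L) * voxel_volume(map$calibration)
}

#' F-actin adjusted fluorescence distribution (nuclei-normalised 3D volume)
#'
#' The 3D counterpart of [adjusted_intensity()]: the segmented F-actin map
#' volume inside each subvolume is divided by the subvolume's nuclear
#' count, and the distribution-to-nuclear ratios are averaged over included
#' subvolumes to give the adjusted fluorescence distribution. Subvolumes
#' with zero nuclei are excluded and reported.
#'
#' @param map A `segmentation_map` from [segment_factin_3d()].
#' @param subvolumes List of [volume_crop()]s (conventionally the 3 x 3
#'   partition from [partition_subvolumes()]).
#' @param nuclei_counts Integer vector of nuclear counts aligned with
#'   `subvolumes` (from [count_nuclei_subvolume()]).
#' @return An object of class `"distribution_result"`: list with
#'   `per_subvolume` (data.frame: subvolume, map_volume_um3, n_nuclei,
#'   ratio, included), `adjusted_distribution`, `excluded_subvolumes`.
#' @export
adjusted_distribution <- function(map, subvolumes, nuclei_counts) {
  stopifnot(inherits(map, "segmentation_map"),
            length(subvolumes) == length(nuclei_counts))
  vols <- vapply(subvolumes, function(sv) map_volume_in(map, sv), numeric(1))
  per <- data.frame(subvolume = seq_along(subvolumes),
                    map_volume_um3 = vols,
                    n_nuclei = as.integer(nuclei_counts),
                    ratio = ifelse(nuclei_counts > 0,
                                   vols / nuclei_counts, NA_real_),
                    included = nuclei_counts > 0)
  if (!any(per$included))
    stop("all subvolumes have zero nuclear count; distribution undefined")
  structure(list(
    per_subvolume = per,
    adjusted_distribution = mean(per$ratio[per$included]),
    excluded_subvolumes = per$subvolume[!per$included]),
    class = "distribution_result")
}

#' @export
print.distribution_result <- function(x, ...) {
  cat(sprintf(
    "<distribution_result> adjusted distribution %.4g um^3/nucleus over %d/%d subvolumes\n",
    x$adjusted_distribution, sum(x$per_subvolume$included),
    nrow(x$per_subvolume)))
  invisible(x)
}

#' Run the full 3D distribution pipeline on one two-channel stack
#'
#' Convenience wrapper: segments the red channel inside `crop`, partitions
#' the crop 3 x 3, counts nuclei per subvolume on the green channel, and
#' returns the adjusted distribution.
#'
#' @inheritParams adjusted_intensity
#' @param crop A [volume_crop()]; defaults to the full stack.
#' @param window,min_feature_um3,grain_um Passed to [segment_factin_3d()].
#' @param z_stride_um Nuclear counting stride (default 8 um).
#' @param ... Passed to [detect_nuclei_section()].
#' @return A `distribution_result` (with the `segmentation_map` attached as
#'   `$map`).
#' @export
distribution_pipeline <- function(red, green, crop = NULL,
                                  window = c(10025, 65540),
                                  min_feature_um3 = 0, grain_um = 0,
                                  z_stride_um = 8, ...) {
  if (is.null(crop)) crop <- full_crop(red)
  map <- segment_factin_3d(red, window = window,
                           min_feature_um3 = min_feature_um3,
                           grain_um = grain_um)
  subs <- partition_subvolumes(crop)
  counts <- vapply(subs, function(sv)
    count_nuclei_subvolume(green, sv, z_stride_um = z_stride_um, ...),
    integer(1))
  res <- adjusted_distribution(map, subs, counts)
  res$map <- map
  res
}
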