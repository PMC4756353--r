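#' Elliptical cross-sectional area from axis diameters
#'
#' Pore cross-sections are treated as ellipses: area =
#' `pi * (short/2) * (long/2)`.
#'
#' @param short_um,long_um Short- and long-axis diameters in micrometres
#'   (both `> 0`; vectorised).
#' @return Area(s) in um^2.
#' @examples
#' ellipse_area(10, 10)  # 78.54, a circle
#' ellipse_area(10, 20)  # 157.08
#' @export
ellipse_area <- function(short_um, long_um) {
  if (any(short_um <= 0) || any(long_um <= 0))
    stop("axis diameters must be positive")
  pi * (short_um / 2) * (long_um / 2)
}

# moment-equivalent ellipse axis diameters (um) of a pixel set;
# xy is an n x 2 matrix of 0-based (x, y) pixel indices
.moment_axes_um <- function(xy, dx, dy) {
  pts <- cbind(xy[, 1] * dx, xy[, 2] * dy)
  cv <- if (nrow(pts) > 1) stats::cov(pts) * (nrow(pts) - 1) / nrow(pts)
        else matrix(0, 2, 2)
  cv <- cv + diag(c(dx^2, dy^2) / 12)  # finite pixel extent
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  c(long = 4 * sqrt(max(ev[1], 0)), short = 4 * sqrt(max(ev[2], 0)))
}

#' Measure pore cross-sections in one optical section
#'
#' Voids are 8-connected components of sub-threshold pixels in the
#' autofluorescence channel. Components touching the XY frame border are
#' artifactually sectioned pores and are excluded from the returned list.
#' Axis diameters are those of the moment-equivalent ellipse (the
#' reproducible analogue of measuring short/long axes by hand) and the
#' cross-sectional area follows from [ellipse_area()].
#'
#' @param stack A [channel_stack()] (autofluorescence channel).
#' @param z 0-based section index.
#' @param af_threshold Intensity below which a pixel is void.
#' @param min_area_um2 Minimum raw pixel-count area for a component to be
#'   considered a pore (suppresses noise speckle), default 20 um^2.
#' @param grain_um In-plane Gaussian pre-smoothing grain (SD = grain/2)
#'   applied before thresholding, so photon noise on the autofluorescent
#'   structure does not perforate pore borders; default 1 um, 0 disables.
#' @param keep_border If `TRUE`, border-touching pores are returned too
#'   (flagged) instead of dropped.
#' @return A data.frame: `section`, `short_um`, `long_um`, `area_um2`
#'   (elliptical), `pixel_area_um2`, `border_touching`.
#' @export
measure_pores_2d <- function(stack, z, af_threshold = 3600,
                             min_area_um2 = 20, grain_um = 1,
                             keep_border = FALSE) {
  stopifnot(is_channel_stack(stack))
  cal <- stack$calibration
  d <- dim(stack$voxels)
  if (z < 0 || z >= d[1]) stop("section index out of range: ", z)
  sec <- stack$voxels[z + 1L, , ]
  if (grain_um > 0) {
    a <- array(sec, dim = c(1L, d[2], d[3]))
    sec <- gaussian_blur_3d(a, grain_um / 2, cal)[1, , ]
  }
  mask <- sec < af_threshold
  empty <- data.frame(section = integer(0), short_um = numeric(0),
                      long_um = numeric(0), area_um2 = numeric(0),
                      pixel_area_um2 = numeric(0),
                      border_touching = logical(0))
  if (!any(mask)) return(empty)
  labels <- label_components_3d(mask)[1, , ]
  k <- max(labels)
  px_area <- cal$dx * cal$dy
  ny <- d[2]; nx <- d[3]
  out <- vector("list", k)
  for (lb in seq_len(k)) {
    ij <- which(labels == lb, arr.ind = TRUE)
    pix_area <- nrow(ij) * px_area
    if (pix_area < min_area_um2) next
    border <- any(ij[, 1] == 1L | ij[, 1] == ny |
                  ij[, 2] == 1L | ij[, 2] == nx)
    if (border && !keep_border) next
    ax <- .moment_axes_um(cbind(ij[, 2] - 1, ij[, 1] - 1), cal$dx, cal$dy)
    out[[lb]] <- data.frame(section = z, short_um = ax["short"],
                            long_um = ax["long"],
                            area_um2 = ellipse_area(ax["short"], ax["long"]),
                            pixel_area_um2 = pix_area,
                            border_touching = border)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# binary erosion by a set of voxel offsets (n x 3 matrix of dz,dy,dx)
.binary_erode <- function(mask, offsets) {
  d <- dim(mask)
  out <- mask
  for (i in seq_len(nrow(offsets))) {
    o <- offsets[i, ]
    if (all(o == 0)) next
    shifted <- array(FALSE, d)
    zs <- max(1, 1 + o[1]):min(d[1], d[1] + o[1])
    ys <- max(1, 1 + o[2]):min(d[2], d[2] + o[2])
    xs <- max(1, 1 + o[3]):min(d[3], d[3] + o[3])
    shifted[zs - o[1], ys - o[2], xs - o[3]] <- mask[zs, ys, xs]
    out <- out & shifted
  }
  out
}

.sphere_offsets <- function(radius_um, cal) {
  rz <- floor(radius_um / cal$dz); ry <- floor(radius_um / cal$dy)
  rx <- floor(radius_um / cal$dx)
  g <- expand.grid(dz = -rz:rz, dy = -ry:ry, dx = -rx:rx)
  keep <- (g$dz * cal$dz)^2 + (g$dy * cal$dy)^2 + (g$dx * cal$dx)^2 <=
    radius_um^2
  as.matrix(g[keep, , drop = FALSE])
}

#' Morphological opening of a 3D mask with a spherical element
#'
#' Optional smoothing of segmented masks (erosion followed by dilation);
#' exposed because some renderers apply a comparable "largest sphere"
#' constraint, but off by default since its exact semantics are uncertain.
#'
#' @param mask Logical 3D array.
#' @param radius_um Sphere radius in micrometres.
#' @param cal A [calibration()].
#' @return Opened logical array.
#' @export
morph_open_3d <- function(mask, radius_um, cal) {
  if (radius_um <= 0) return(mask)
  off <- .sphere_offsets(radius_um, cal)
  eroded <- .binary_erode(mask, off)
  !(.binary_erode(!eroded, off))
}

#' 3D pore (void) volume by negative-imprint mask subtraction
#'
#' Reproduces the void-volume procedure: (1) segment the autofluorescent
#' (AF) structural foreground with Gaussian pre-smoothing (SD = grain/2),
#' an intensity minimum cutoff (3,600 by default, adjustable per treatment
#' pair) and a minimum component volume; (2) form a solid mask over the
#' crop (value 20,000 for file export; internally boolean); (3) subtract
#' the AF foreground from the solid mask, carving a negative imprint of the
#' structure; (4) segment the resulting void field with its own grain,
#' automatic (Otsu) or fixed cutoff and minimum component volume. When
#' smoothing and size/intensity filters are all disabled the void mask is
#' exactly the boolean complement of the AF foreground, so AF + void
#' volumes tile the crop.
#'
#' @param stack A [channel_stack()] (autofluorescence channel).
#' @param crop A [volume_crop()]; defaults to the full stack.
#' @param af_params List: `grain_um` (2), `cutoff` (3600),
#'   `min_volume_um3` (10).
#' @param void_params List: `grain_um` (0.481), `cutoff` (`"auto"` = Otsu
#'   on the void field, or numeric), `min_volume_um3` (10).
#' @param mask_value Solid-mask intensity used when exporting the void
#'   field (default 20000); does not affect measured volumes.
#' @param opening_radius_um Optional [morph_open_3d()] radius applied to
#'   the AF foreground (default 0 = off).
#' @return An object of class `"void_volume_result"`: list with `voids`
#'   (data.frame: label, n_voxels, volume_um3), `total_void_volume_um3`,
#'   `af_volume_um3`, `crop_volume_um3`, `void_cutoff_used`, masks
#'   (`af_mask`, `void_mask`) and the parameter lists.
#' @export
void_volume_3d <- function(stack, crop = NULL,
                           af_params = list(grain_um = 2, cutoff = 3600,
                                            min_volume_um3 = 10),
                           void_params = list(grain_um = 0.481,
                                              cutoff = "auto",
                                              min_volume_um3 = 10),
                           mask_value = 20000,
                           opening_radius_um = 0) {
  stopifnot(is_channel_stack(stack))
  if (is.null(crop)) crop <- full_crop(stack)
  cal <- stack$calibration
  arr <- crop_stack(stack, crop)
  vv <- voxel_volume(cal)
  defaults <- function(given, def) utils::modifyList(def, given)
  afp <- defaults(af_params, list(grain_um = 2, cutoff = 3600,
                                  min_volume_um3 = 10))
  vdp <- defaults(void_params, list(grain_um = 0.481, cutoff = "auto",
                                    min_volume_um3 = 10))

  af_field <- if (afp$grain_um > 0)
    gaussian_blur_3d(arr, afp$grain_um / 2, cal) else arr
  af_mask <- af_field > afp$cutoff
  if (opening_radius_um > 0)
    af_mask <- morph_open_3d(af_mask, opening_radius_um, cal)
  if (afp$min_volume_um3 > 0) {
    lab <- label_components_3d(af_mask)
    k <- attr(lab, "n_components")
    if (k > 0) {
      counts <- tabulate(lab[lab > 0L], nbins = k)
      small <- which(counts * vv < afp$min_volume_um3)
      if (length(small)) af_mask[lab %in% small] <- FALSE
    }
  }

  plain_complement <- vdp$grain_um == 0 && vdp$min_volume_um3 == 0
  void_cutoff_used <- NA_real_
  if (plain_complement) {
    void_mask <- !af_mask
  } else {
    void_field <- mask_value * as.numeric(!af_mask)
    dim(void_field) <- dim(af_mask)
    if (vdp$grain_um > 0)
      void_field <- gaussian_blur_3d(void_field, vdp$grain_um / 2, cal)
    void_cutoff_used <- if (identical(vdp$cutoff, "auto")) {
      EBImage::otsu(matrix(void_field / mask_value,
                           nrow = dim(void_field)[2]),
                    range = c(0, 1), levels = 256L) * mask_value
    } else as.numeric(vdp$cutoff)
    void_mask <- void_field > void_cutoff_used
  }

  lab <- label_components_3d(void_mask)
  k <- attr(lab, "n_components")
  if (k > 0) {
    counts <- tabulate(lab[lab > 0L], nbins = k)
    voids <- data.frame(label = seq_len(k), n_voxels = counts,
                        volume_um3 = counts * vv)
    if (!plain_complement && vdp$min_volume_um3 > 0) {
      drop <- voids$label[voids$volume_um3 < vdp$min_volume_um3]
      if (length(drop)) {
        void_mask[lab %in% drop] <- FALSE
        voids <- voids[!voids$label %in% drop, , drop = FALSE]
      }
    }
  } else {
    voids <- data.frame(label = integer(0), n_voxels = integer(0),
                        volume_um3 = numeric(0))
  }
  structure(list(
    voids = voids,
    total_void_volume_um3 = sum(voids$volume_um3),
    af_volume_um3 = sum(af_mask) * vv,
    crop_volume_um3 = crop_n_voxels(crop) * vv,
    void_cutoff_used = void_cutoff_used,
    af_mask = af_mask, void_mask = void_mask,
    af_params = afp, void_params = vdp, mask_value = mask_value),
    class = "void_volume_result")
}

#' @export
print.void_volume_result <- function(x, ...) {
  cat(sprintf(
    "<void_volume_result> %d voids, total %.6g um^3 (AF %.6g, crop %.6g um^3)\n",
    nrow(x$voids), x$total_void_volume_um3, x$af_volume_um3,
    x$crop_volume_um3))
  if (!is.na(x$void_cutoff_used))
    cat(sprintf("  automatic void cutoff used: %.4g\n", x$void_cutoff_used))
  invisible(x)
}

#' Summarise pore morphometry for a control/treated pair
#'
#' @param control,treated Lists with elements `areas_um2` (vector of 2D
#'   pore areas) and `volumes_um3` (vector of per-stack total void
#'   volumes); either element may be absent.
#' @return A list with `table` (metric, per-condition mean and SD, n,
#'   group-mean percent change and its nearest-integer rounding) and
#'   `notes` (e.g. when the per-stack pore count falls outside the
#'   conventional 4-12 range).
#' @export
pore_summary <- function(control, treated) {
  if (!length(control) || !length(treated)) stop("empty inputs")
  notes <- character(0)
  one <- function(metric, cv, tv) {
    if (is.null(cv) || is.null(tv)) return(NULL)
    if (!length(cv) || !length(tv)) stop("empty measurements for ", metric)
    pc <- percent_change(group_means = c(control = mean(cv),
                                         treated = mean(tv)))
    data.frame(metric = metric,
               control_mean = mean(cv), control_sd = stats::sd(cv),
               treated_mean = mean(tv), treated_sd = stats::sd(tv),
               n_control = length(cv), n_treated = length(tv),
               pct_change = pc, pct_change_rounded = round(pc))
  }
  tab <- rbind(one("pore_area_2d_um2", control$areas_um2, treated$areas_um2),
               one("pore_volume_3d_um3", control$volumes_um3,
                   treated$volumes_um3))
  na <- length(control$areas_um2)
  if (na && (na < 4 || na > 12))
    notes <- c(notes, sprintf(
      "control pore count %d outside the conventional 4-12 per z-stack", na))
  nt <- length(treated$areas_um2)
  if (nt && (nt < 4 || nt > 12))
    notes <- c(notes, sprintf(
      "treated pore count %d outside the conventional 4-12 per z-stack", nt))
  list(table = tab, notes = notes)
}
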