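#' Mean grey value of an ROI at one section
#'
#' @inheritParams extract_roi
#' @return Arithmetic mean of the ROI's pixel intensities.
#' @export
roi_mean_intensity <- function(stack, roi, z) {
  mean(extract_roi(stack, roi, z))
}

#' F-actin adjusted fluorescence intensity (nuclei-normalised ROI density)
#'
#' For each ROI, the mean grey value of the red (F-actin) channel is
#' averaged over optical sections sampled every `intensity_stride_um`, then
#' divided by the nuclear count of the same ROI (green channel, sampled
#' every `nuclei_stride_um`), giving an intensity-to-nuclear ratio. The
#' grand mean of the ratios over ROIs — all included ROIs weighted equally —
#' is the adjusted fluorescence intensity, a per-cell F-actin density
#' measure robust to variation in cell sampling. ROIs whose nuclear count
#' is zero are excluded from the grand mean (the ratio is undefined) and
#' reported.
#'
#' @param red,green [channel_stack()]s of the F-actin and
#'   autofluorescence + nuclei channels (same dimensions).
#' @param rois List of [roi_spec()] (conventionally 5).
#' @param intensity_stride_um Section sampling interval for intensity
#'   (default 2 um).
#' @param nuclei_stride_um Section sampling interval for nuclear counting
#'   (default 8 um).
#' @param z_start First sampled section (0-based).
#' @param ... Passed to [detect_nuclei_section()] via [count_nuclei_roi()].
#' @return An object of class `"density_result"`: list with `per_roi`
#'   (data.frame: roi, mean_intensity, n_nuclei, ratio, included,
#'   physical_area_um2), `adjusted_intensity`, `excluded_rois`,
#'   `intensity_sections`, `nuclei_stride_um`.
#' @export
adjusted_intensity <- function(red, green, rois,
                               intensity_stride_um = 2,
                               nuclei_stride_um = 8,
                               z_start = 0L, ...) {
  stopifnot(is_channel_stack(red), is_channel_stack(green),
            length(rois) >= 1)
  if (!identical(dim(red$voxels), dim(green$voxels)))
    stop("red and green stacks must have identical dimensions")
  cal <- red$calibration
  step <- .stride_step(intensity_stride_um, cal)
  nz <- dim(red$voxels)[1]
  sections <- seq(z_start, nz - 1L, by = step)
  nstep <- .stride_step(nuclei_stride_um, cal)
  nsections <- seq(z_start, nz - 1L, by = nstep)
  # detect once per sampled section, then assign to ROIs by centroid
  dets <- do.call(rbind, lapply(nsections, function(z)
    detect_nuclei_section(green, z, ...)))
  per <- lapply(seq_along(rois), function(i) {
    roi <- rois[[i]]
    mi <- mean(vapply(sections, function(z)
      roi_mean_intensity(red, roi, z), numeric(1)))
    n <- if (is.null(dets) || !nrow(dets)) 0L else {
      xi <- round(dets$x); yi <- round(dets$y)
      sum(xi >= roi$x0 & xi < roi$x0 + roi$width &
          yi >= roi$y0 & yi < roi$y0 + roi$height)
    }
    data.frame(roi = i, mean_intensity = mi, n_nuclei = n,
               ratio = if (n > 0) mi / n else NA_real_,
               included = n > 0,
               physical_area_um2 = roi$physical_area)
  })
  per <- do.call(rbind, per)
  if (!any(per$included))
    stop("all ROIs have zero nuclear count; adjusted intensity undefined")
  structure(list(
    per_roi = per,
    adjusted_intensity = mean(per$ratio[per$included]),
    excluded_rois = per$roi[!per$included],
    intensity_sections = sections,
    nuclei_stride_um = nuclei_stride_um), class = "density_result")
}

#' @export
print.density_result <- function(x, ...) {
  cat(sprintf("<density_result> adjusted intensity %.4g over %d/%d ROIs\n",
              x$adjusted_intensity, sum(x$per_roi$included),
              nrow(x$per_roi)))
  invisible(x)
}

#' Mean autofluorescence intensity over ROIs and sampled sections
#'
#' The same ROI sampling as [adjusted_intensity()] applied to the green
#' (autofluorescence) channel, without nuclear normalisation: ROI mean grey
#' values are averaged over sampled sections and then over ROIs, yielding
#' one mean autofluorescence intensity per stack (condition).
#'
#' @inheritParams adjusted_intensity
#' @param green A [channel_stack()] of the autofluorescence channel.
#' @param stride_um Section sampling interval (default 2 um).
#' @return A list with `mean_af_intensity` and `per_roi` (data.frame).
#' @export
autofluorescence_intensity <- function(green, rois, stride_um = 2,
                                       z_start = 0L) {
  stopifnot(is_channel_stack(green), length(rois) >= 1)
  cal <- green$calibration
  step <- .stride_step(stride_um, cal)
  nz <- dim(green$voxels)[1]
  sections <- seq(z_start, nz - 1L, by = step)
  per <- vapply(rois, function(roi)
    mean(vapply(sections, function(z)
      roi_mean_intensity(green, roi, z), numeric(1))), numeric(1))
  list(mean_af_intensity = mean(per),
       per_roi = data.frame(roi = seq_along(rois), mean_intensity = per))
}
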