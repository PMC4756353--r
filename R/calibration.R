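#' Voxel calibration
#'
#' Describes the physical size of a voxel and the intensity bit depth of a
#' channel stack. All physical quantities in this package are micrometres
#' (lengths), square micrometres (areas) and cubic micrometres (volumes);
#' intensities are raw detector grey values.
#'
#' @param dx,dy,dz Voxel edge lengths along x, y and z, in micrometres.
#'   The default (0.24, 0.24, 1) matches a typical two-photon acquisition
#'   of a 246 um field at 1024 x 1024 pixels with 1 um optical sectioning.
#' @param bit_depth Intensity bit depth, 8 or 16.
#' @return An object of class `"calibration"`: a list with elements `dx`,
#'   `dy`, `dz`, `bit_depth` and `max_intensity` (`2^bit_depth - 1`).
#' @examples
#' cal <- calibration()
#' cal$max_intensity  # 65535
#' @export
calibration <- function(dx = 0.24, dy = 0.24, dz = 1, bit_depth = 16L) {
  stopifnot(is.numeric(dx), is.numeric(dy), is.numeric(dz),
            dx > 0, dy > 0, dz > 0)
  if (!bit_depth %in% c(8L, 16L))
    stop("bit_depth must be 8 or 16, got ", bit_depth)
  structure(
    list(dx = as.numeric(dx), dy = as.numeric(dy), dz = as.numeric(dz),
         bit_depth = as.integer(bit_depth),
         max_intensity = as.integer(2^bit_depth - 1)),
    class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("<calibration> voxel %.4g x %.4g x %.4g um (x,y,z), %d-bit\n",
              x$dx, x$dy, x$dz, x$bit_depth))
  invisible(x)
}

#' Voxel volume of a calibration
#'
#' @param cal A [calibration()].
#' @return Voxel volume in cubic micrometres (`dx * dy * dz`).
#' @export
voxel_volume <- function(cal) cal$dx * cal$dy * cal$dz

#' Convert a physical position to a voxel grid index
#'
#' Maps a non-negative physical position along one axis to the 0-based index
#' of the voxel containing it: `floor(position / voxel_size)`. Grid indices
#' throughout this package are 0-based with half-open extents; add 1 to
#' obtain an R array subscript.
#'
#' @param position_um Physical position(s) in micrometres, `>= 0`.
#' @param axis One of `"x"`, `"y"`, `"z"`.
#' @param cal A [calibration()].
#' @return Integer 0-based voxel index (vectorised over `position_um`).
#' @examples
#' cal <- calibration()
#' physical_to_index(25, "z", cal)  # 25
#' physical_to_index(10, "x", cal)  # 41
#' @export
physical_to_index <- function(position_um, axis = c("x", "y", "z"), cal) {
  axis <- match.arg(axis)
  if (any(position_um < 0)) stop("position_um must be non-negative")
  step <- switch(axis, x = cal$dx, y = cal$dy, z = cal$dz)
  as.integer(floor(position_um / step))
}
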