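#' Real-valued 3D volume
#'
#' A tomogram or sub-tomogram: a finite real 3D array indexed `(z, y, x)`
#' (beam/optical axis = z, tilt axis = y) together with its voxel size in
#' Angstroms.
#'
#' @param data Numeric 3D array, dimensions `(nz, ny, nx)`, all finite.
#' @param voxel_size_A Voxel edge length in Angstroms (> 0).
#' @return An object of class `wf_volume` with fields `data` and
#'   `voxel_size_A`.
#' @export
volume <- function(data, voxel_size_A = 1) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3D array indexed (z, y, x)")
  }
  if (any(dim(data) < 1L)) stop("all volume dimensions must be >= 1")
  if (!all(is.finite(data))) stop("volume values must be finite")
  if (!is.numeric(voxel_size_A) || length(voxel_size_A) != 1L ||
      voxel_size_A <= 0) {
    stop("`voxel_size_A` must be a single positive number")
  }
  structure(list(data = data, voxel_size_A = voxel_size_A),
            class = "wf_volume")
}

#' @export
print.wf_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<wf_volume %d x %d x %d (z,y,x), %.3g A/voxel>\n",
              d[1], d[2], d[3], x$voxel_size_A))
  invisible(x)
}

# accept either a wf_volume or a bare 3D array
as_volume <- function(x, voxel_size_A = 1) {
  if (inherits(x, "wf_volume")) return(x)
  volume(x, voxel_size_A)
}

vol_data <- function(x) if (inherits(x, "wf_volume")) x$data else x

#' Tilt scheme
#'
#' The ordered set of tilt angles (degrees) at which projections are
#' recorded, rotating about the microscope tilt axis (y by convention).
#'
#' @param angles_deg Strictly increasing numeric vector, all `|angle| <= 90`.
#' @return An object of class `wf_tilt_scheme`.
#' @export
tilt_scheme <- function(angles_deg) {
  if (length(angles_deg) == 0L) stop("tilt scheme must be non-empty")
  if (!all(is.finite(angles_deg))) stop("tilt angles must be finite")
  if (any(diff(angles_deg) <= 0)) {
    stop("tilt angles must be strictly increasing")
  }
  if (any(abs(angles_deg) > 90)) stop("tilt angles must satisfy |angle| <= 90")
  structure(list(angles_deg = as.numeric(angles_deg), tilt_axis = "y"),
            class = "wf_tilt_scheme")
}

#' @export
print.wf_tilt_scheme <- function(x, ...) {
  a <- x$angles_deg
  cat(sprintf("<wf_tilt_scheme %d angles, %.4g..%.4g deg, tilt axis %s>\n",
              length(a), min(a), max(a), x$tilt_axis))
  invisible(x)
}

#' Tilt series
#'
#' A stack of 2D projection images, one per tilt angle.  Images are `(y, x)`
#' matrices stored as an `(ny, nx, P)` array in acquisition order.
#'
#' @param images Numeric 3D array `(ny, nx, P)`; all values finite.
#' @param scheme A [tilt_scheme()] with `P` angles.
#' @param pixel_size_A Pixel size in Angstroms (> 0).
#' @return An object of class `wf_tilt_series`.
#' @export
tilt_series <- function(images, scheme, pixel_size_A = 1) {
  if (!is.array(images) || length(dim(images)) != 3L) {
    stop("`images` must be an (ny, nx, P) array")
  }
  if (!all(is.finite(images))) stop("tilt series values must be finite")
  if (!inherits(scheme, "wf_tilt_scheme")) {
    stop("`scheme` must be a wf_tilt_scheme")
  }
  if (dim(images)[3] != length(scheme$angles_deg)) {
    stop("number of images must equal number of tilt angles")
  }
  if (pixel_size_A <= 0) stop("`pixel_size_A` must be positive")
  structure(
    list(images = images, scheme = scheme, pixel_size_A = pixel_size_A),
    class = "wf_tilt_series"
  )
}

#' @export
print.wf_tilt_series <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("<wf_tilt_series %d projections of %d x %d, %.3g A/pixel>\n",
              d[3], d[1], d[2], x$pixel_size_A))
  invisible(x)
}

n_tilts <- function(ts) dim(ts$images)[3]
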