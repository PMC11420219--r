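#' @name fourier
#' @title Fourier-domain wedge machinery
#'
#' @description
#' Binary missing-wedge masks, rotated wedge masks evaluated analytically on
#' rotated frequency coordinates, mask application, Haar-uniform rotations
#' and trilinear volume rotation.
#'
#' Geometry: with the tilt axis along y and the beam along z, a tilt range of
#' `+/- alpha_max` measures every Fourier component whose `(k_x, k_z)`
#' direction lies within `alpha_max` of the `k_x` axis.  The missing wedge is
#' therefore `|k_z| > tan(alpha_max) * |k_x|` (independent of `k_y`); points
#' on the boundary count as measured.
NULL

# ---- unitary FFT helpers ----------------------------------------------------

fft_u <- function(x) stats::fft(x) / sqrt(length(x))

ifft_u <- function(x) stats::fft(x, inverse = TRUE) / sqrt(length(x))

# centered frequency indices for one dimension: -floor(n/2) .. ceil(n/2)-1,
# arranged so that index floor(n/2)+1 (1-based) is DC in the shifted layout
centered_freqs <- function(n) seq_len(n) - 1 - n %/% 2

# 1-based position of -k for each centered position (the -n/2 plane of an
# even dimension is its own partner)
mirror_index <- function(n) {
  k <- centered_freqs(n)
  vapply(k, function(kk) {
    kn <- -kk
    if (kn > max(k)) kn <- min(k)
    which(k == kn)
  }, integer(1))
}

# reorder a shifted (DC-centered) array to the natural fft layout
ifftshift3 <- function(x) {
  d <- dim(x)
  idx <- lapply(d, function(n) c((n %/% 2 + 1):n, seq_len(n %/% 2)))
  x[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

fftshift3 <- function(x) {
  d <- dim(x)
  idx <- lapply(d, function(n) {
    c((n - n %/% 2 + 1):n, seq_len(n - n %/% 2))
  })
  x[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

# ---- wedge masks ------------------------------------------------------------

new_wedge_mask <- function(data, alpha_max_deg, orientation = NULL) {
  structure(
    list(data = data, alpha_max_deg = alpha_max_deg,
         orientation = orientation),
    class = "wf_wedge_mask"
  )
}

#' @export
print.wf_wedge_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<wf_wedge_mask %d x %d x %d, alpha_max %.3g deg, %s, %.1f%% zeroed>\n",
    d[1], d[2], d[3], x$alpha_max_deg,
    if (is.null(x$orientation)) "axis-aligned" else "rotated",
    100 * mean(x$data == 0)
  ))
  invisible(x)
}

check_alpha <- function(alpha_max_deg) {
  if (!is.numeric(alpha_max_deg) || length(alpha_max_deg) != 1L ||
      alpha_max_deg <= 0 || alpha_max_deg >= 90) {
    stop("`alpha_max_deg` must lie in (0, 90)")
  }
}

#' Missing-wedge mask
#'
#' Binary 3D Fourier-domain mask, fftshift-centered (DC at the center voxel),
#' that is 0 exactly on the missing wedge `|k_z| > tan(alpha_max) * |k_x|`
#' and 1 elsewhere.  The mask is symmetric under point inversion, so applying
#' it to the transform of a real volume returns a real volume.
#'
#' @param shape Integer vector `(nz, ny, nx)`.
#' @param alpha_max_deg Maximal tilt angle in degrees, in (0, 90).
#' @return A `wf_wedge_mask`.
#' @export
wedge_mask <- function(shape, alpha_max_deg) {
  check_alpha(alpha_max_deg)
  shape <- as.integer(shape)
  if (length(shape) != 3L) stop("`shape` must be (nz, ny, nx)")
  kz <- centered_freqs(shape[1])
  kx <- centered_freqs(shape[3])
  t <- tan(alpha_max_deg * pi / 180)
  keep_zx <- outer(abs(kz), abs(kx), function(az, ax) az <= t * ax)
  m <- array(0, dim = shape)
  for (ix in seq_len(shape[3])) {
    m[, , ix] <- matrix(as.numeric(keep_zx[, ix]), shape[1], shape[2])
  }
  new_wedge_mask(m, alpha_max_deg)
}

#' Rotated missing-wedge mask
#'
#' Evaluates the wedge inequality analytically at the rotated frequency
#' coordinates `R^-1 k` (no resampling of a binary grid).  The identity
#' rotation reproduces [wedge_mask()] bit for bit.
#'
#' @inheritParams wedge_mask
#' @param phi An [euler_angles()] rotation (z-y-z intrinsic, radians).
#' @return A `wf_wedge_mask`.
#' @export
rotated_wedge_mask <- function(shape, alpha_max_deg, phi) {
  check_alpha(alpha_max_deg)
  shape <- as.integer(shape)
  R <- euler_to_matrix(phi)
  kz <- centered_freqs(shape[1])
  ky <- centered_freqs(shape[2])
  kx <- centered_freqs(shape[3])
  # full (kx, ky, kz) grids in (z, y, x) array order
  KZ <- array(kz, dim = shape)
  KY <- array(rep(ky, each = shape[1]), dim = shape)
  KX <- array(rep(kx, each = shape[1] * shape[2]), dim = shape)
  # q = R^T k, wedge test on (q_x, q_z)
  qx <- R[1, 1] * KX + R[2, 1] * KY + R[3, 1] * KZ
  qz <- R[1, 3] * KX + R[2, 3] * KY + R[3, 3] * KZ
  t <- tan(alpha_max_deg * pi / 180)
  m <- array(as.numeric(abs(qz) <= t * abs(qx)), dim = shape)
  # enforce point-inversion symmetry so masked real volumes stay real: on
  # even-sized grids the Nyquist planes are their own negation partners and
  # the analytically evaluated rotated wedge need not be symmetric there; a
  # point counts as measured only if its conjugate partner is measured too
  mir <- lapply(shape, mirror_index)
  m <- pmin(m, m[mir[[1]], mir[[2]], mir[[3]]])
  # DC is always measured
  m[shape[1] %/% 2 + 1, shape[2] %/% 2 + 1, shape[3] %/% 2 + 1] <- 1
  new_wedge_mask(array(m, dim = shape), alpha_max_deg, orientation = phi)
}

#' Apply a Fourier mask to a volume
#'
#' Returns the real part of `F^-1 (mask * F vol)` computed with the unitary
#' FFT.  Binary masks make this idempotent and energy non-increasing.
#'
#' @param vol A [volume()] or 3D array.
#' @param mask A `wf_wedge_mask` (or 0/1 array, fftshift-centered) of the
#'   same shape.
#' @return Same type as `vol`.
#' @export
apply_mask <- function(vol, mask) {
  v <- vol_data(vol)
  m <- if (inherits(mask, "wf_wedge_mask")) mask$data else mask
  if (!identical(dim(v), dim(m))) {
    stop("volume and mask shapes must match")
  }
  out <- Re(ifft_u(ifftshift3(m) * fft_u(v)))
  if (inherits(vol, "wf_volume")) volume(out, vol$voxel_size_A) else out
}

# complement mask: measured <-> missing
complement_mask <- function(mask) {
  new_wedge_mask(1 - mask$data, mask$alpha_max_deg, mask$orientation)
}

# ---- rotations --------------------------------------------------------------

#' Euler angles (z-y-z intrinsic, radians)
#'
#' @param phi1,theta,phi2 Rotation angles in radians.
#' @return An object of class `wf_euler`.
#' @export
euler_angles <- function(phi1 = 0, theta = 0, phi2 = 0) {
  stopifnot(is.finite(phi1), is.finite(theta), is.finite(phi2))
  structure(list(phi1 = phi1, theta = theta, phi2 = phi2),
            class = "wf_euler")
}

rot_z <- function(a) {
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

rot_y <- function(a) {
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}

#' Rotation matrix of z-y-z intrinsic Euler angles
#'
#' @param phi An [euler_angles()] object.
#' @return A 3x3 rotation matrix acting on `(x, y, z)` column vectors.
#' @export
euler_to_matrix <- function(phi) {
  stopifnot(inherits(phi, "wf_euler"))
  rot_z(phi$phi1) %*% rot_y(phi$theta) %*% rot_z(phi$phi2)
}

matrix_to_euler <- function(R) {
  theta <- acos(max(-1, min(1, R[3, 3])))
  if (abs(sin(theta)) < 1e-12) {
    # gimbal-locked: fold everything into phi1
    euler_angles(atan2(R[2, 1], R[1, 1]), theta, 0)
  } else {
    euler_angles(atan2(R[2, 3], R[1, 3]), theta, atan2(R[3, 2], -R[3, 1]))
  }
}

#' Draw a Haar-uniform 3D rotation
#'
#' Uses the uniform-quaternion construction (four standard normals,
#' normalized) and converts to z-y-z Euler angles.  Uses R's global RNG;
#' seed with [set.seed()] for reproducibility.
#'
#' @return An [euler_angles()] object.
#' @export
sample_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z),     2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2),     2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x),     1 - 2 * (x^2 + y^2)
  ), 3, 3)
  matrix_to_euler(R)
}

#' Rotate a cubic volume
#'
#' Trilinear resampling about the cube center.  Samples falling outside the
#' cube are filled with the cube mean (`fill = "mean"`) or zero
#' (`fill = "zero"`).
#'
#' @param vol Cubic [volume()] or 3D array.
#' @param phi An [euler_angles()] rotation to apply to the volume.
#' @param fill Out-of-cube fill rule, `"mean"` or `"zero"`.
#' @return Same type as `vol`.
#' @export
rotate_volume <- function(vol, phi, fill = c("mean", "zero")) {
  fill <- match.arg(fill)
  v <- vol_data(vol)
  d <- dim(v)
  if (length(unique(d)) != 1L) stop("`vol` must be cubic")
  fv <- if (fill == "mean") mean(v) else 0
  R <- euler_to_matrix(phi)
  out <- array(cpp_rotate_trilinear(as.numeric(v), d[1], R, fv), dim = d)
  if (inherits(vol, "wf_volume")) volume(out, vol$voxel_size_A) else out
}
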