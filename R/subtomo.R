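#' Plan a sliding-window sub-tomogram grid
#'
#' Corner offsets of overlapping cubes covering the whole volume: stride is
#' `cube_size - overlap`, and the last window on each axis is clamped to the
#' boundary so every voxel is covered at least once.
#'
#' @param vol_shape Integer `(nz, ny, nx)`.
#' @param cube_size Cube side (<= each dimension).
#' @param overlap Overlap in voxels, `0 <= overlap < cube_size`.
#' @return List of 0-based integer corners `(z0, y0, x0)`.
#' @export
plan_grid <- function(vol_shape, cube_size, overlap = 0) {
  vol_shape <- as.integer(vol_shape)
  cube_size <- as.integer(cube_size)
  overlap <- as.integer(overlap)
  if (any(cube_size > vol_shape)) {
    stop("`cube_size` must not exceed any volume dimension")
  }
  if (overlap < 0 || overlap >= cube_size) {
    stop("`overlap` must satisfy 0 <= overlap < cube_size")
  }
  stride <- cube_size - overlap
  axis_starts <- function(n) {
    s <- seq(0L, n - cube_size, by = stride)
    if (s[length(s)] != n - cube_size) s <- c(s, n - cube_size)
    s
  }
  zs <- axis_starts(vol_shape[1])
  ys <- axis_starts(vol_shape[2])
  xs <- axis_starts(vol_shape[3])
  g <- expand.grid(z0 = zs, y0 = ys, x0 = xs, KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(g)), function(i) as.integer(unlist(g[i, ])))
}

# FFT-based Gaussian blur with periodic boundaries
gaussian_blur3 <- function(x, sigma) {
  if (sigma <= 0) return(x)
  d <- dim(x)
  kern1 <- function(n) {
    k <- centered_freqs(n)[c((n %/% 2 + 1):n, seq_len(n %/% 2))]
    g <- exp(-(pmin(abs(k), n - abs(k)))^2 / (2 * sigma^2))
    g / sum(g)
  }
  # separable: multiply the 3D FFT by the product of 1D kernel FFTs
  K <- outer(outer(stats::fft(kern1(d[1])), stats::fft(kern1(d[2]))),
             stats::fft(kern1(d[3])))
  Re(stats::fft(stats::fft(x) * K, inverse = TRUE)) / prod(d)
}

#' Content mask of the non-empty regions
#'
#' Gaussian-smooths `|vol - median(vol)|` and thresholds at the given
#' percentile of the smoothed field; used to restrict model fitting to
#' cubes that contain sample rather than empty ice.  Invariant to affine
#' intensity rescaling of the input.
#'
#' @param vol A [volume()] or 3D array.
#' @param smooth_sigma Gaussian sigma in voxels.
#' @param percentile Threshold percentile in (0, 100).
#' @return A binary 3D array of the same shape.
#' @export
content_mask <- function(vol, smooth_sigma = 3, percentile = 70) {
  if (percentile <= 0 || percentile >= 100) {
    stop("`percentile` must lie in (0, 100)")
  }
  v <- vol_data(vol)
  dev <- abs(v - median(v))
  if (all(dev == 0)) {
    warning("constant volume: content mask is empty")
    return(array(0, dim = dim(v)))
  }
  sm <- gaussian_blur3(dev, smooth_sigma)
  thr <- quantile(sm, percentile / 100, names = FALSE)
  array(as.numeric(sm > thr), dim = dim(v))
}

#' Filter grid positions by content fraction
#'
#' Keeps positions whose cube contains at least `min_fraction` sample
#' according to the mask.
#'
#' @param positions List of corners from [plan_grid()].
#' @param mask Binary 3D array from [content_mask()].
#' @param cube_size Cube side used for the grid.
#' @param min_fraction Required sample fraction in `[0, 1]`.
#' @return Filtered list of positions.
#' @export
filter_positions <- function(positions, mask, cube_size, min_fraction = 0.4) {
  if (min_fraction < 0 || min_fraction > 1) {
    stop("`min_fraction` must lie in [0, 1]")
  }
  keep <- vapply(positions, function(p) {
    cube <- mask[p[1] + seq_len(cube_size), p[2] + seq_len(cube_size),
                 p[3] + seq_len(cube_size)]
    mean(cube) >= min_fraction
  }, logical(1))
  positions[keep]
}

extract_cube <- function(v, p, s) {
  v[p[1] + seq_len(s), p[2] + seq_len(s), p[3] + seq_len(s), drop = FALSE]
}

#' Extract sub-tomogram pairs
#'
#' Copies same-position cubes from the two half-reconstructions.  Each pair
#' carries its grid position and normalization statistics (mean and sd of
#' the half-0 cube), used to standardize model inputs and undo the
#' standardization before reassembly.
#'
#' @param vol0,vol1 Two [volume()]s (or arrays) of identical shape.
#' @param positions List of corners from [plan_grid()].
#' @param cube_size Cube side.
#' @return List of `wf_subtomo_pair` objects with fields `v0`, `v1`, `pos`,
#'   `norm_stats`.
#' @export
extract_pairs <- function(vol0, vol1, positions, cube_size) {
  a0 <- vol_data(vol0)
  a1 <- vol_data(vol1)
  if (!identical(dim(a0), dim(a1))) stop("volume shapes must match")
  d <- dim(a0)
  lapply(positions, function(p) {
    if (any(p < 0L) || any(p + cube_size > d)) {
      stop("grid position out of bounds")
    }
    c0 <- extract_cube(a0, p, cube_size)
    c1 <- extract_cube(a1, p, cube_size)
    m <- mean(c0)
    s <- sd(as.numeric(c0))
    if (!is.finite(s) || s == 0) {
      stop("constant sub-tomogram: cannot standardize (sd = 0)")
    }
    structure(list(v0 = c0, v1 = c1, pos = p,
                   norm_stats = c(mean = m, sd = s)),
              class = "wf_subtomo_pair")
  })
}

#' Reassemble cubes into a full volume
#'
#' Every voxel is the uniform average of all cubes covering it; voxels
#' covered by exactly one cube equal that cube's values exactly.  Errors if
#' the grid does not cover the whole output volume.
#'
#' @param cubes List of cubic 3D arrays (all the same size).
#' @param positions Matching list of corners.
#' @param out_shape Integer `(nz, ny, nx)`.
#' @return A 3D array of shape `out_shape`.
#' @export
reassemble <- function(cubes, positions, out_shape) {
  stopifnot(length(cubes) == length(positions), length(cubes) > 0)
  s <- dim(cubes[[1]])[1]
  acc <- array(0, dim = out_shape)
  cnt <- array(0, dim = out_shape)
  for (i in seq_along(cubes)) {
    p <- positions[[i]]
    iz <- p[1] + seq_len(s); iy <- p[2] + seq_len(s); ix <- p[3] + seq_len(s)
    acc[iz, iy, ix] <- acc[iz, iy, ix] + cubes[[i]]
    cnt[iz, iy, ix] <- cnt[iz, iy, ix] + 1
  }
  if (any(cnt == 0)) stop("grid does not cover the output volume")
  acc / cnt
}
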