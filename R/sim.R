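#' Regular tilt scheme
#'
#' Angles `min, min + step, ...` up to and including `max` whenever
#' `max - min` is an integer multiple of `step`.
#'
#' @param min_deg,max_deg Range of tilt angles in degrees (`min < max`).
#' @param step_deg Angular increment in degrees (> 0).
#' @return A [tilt_scheme()].
#' @examples
#' length(make_tilt_scheme(-60, 60, 3)$angles_deg) # 41
#' @export
make_tilt_scheme <- function(min_deg, max_deg, step_deg) {
  if (!is.numeric(step_deg) || step_deg <= 0) {
    stop("`step_deg` must be positive")
  }
  if (min_deg >= max_deg) stop("`min_deg` must be smaller than `max_deg`")
  tilt_scheme(seq(min_deg, max_deg, by = step_deg))
}

#' Phantom specification
#'
#' Describes a random geometric phantom: bright spheres, rods (cylinders at
#' random orientation) and spherical shells on a zero background, emulating
#' globular particles, filaments and membrane-bounded compartments.  All
#' objects are placed inside a central cylinder about the tilt (y) axis with
#' a safety margin, so the phantom stays in field when projected at tilt
#' angles up to about 70 degrees.
#'
#' @param shape Integer `(nz, ny, nx)`, every dimension >= 8.
#' @param n_spheres,n_rods,n_shells Object counts (>= 0).
#' @param intensity Range of object intensities, `c(lo, hi)`, lo > 0.
#' @param sphere_radius Range of sphere radii in voxels, `c(lo, hi)`; the
#'   default scales with the grid.
#' @param seed Integer seed making the phantom deterministic.
#' @return An object of class `wf_phantom_spec`.
#' @export
phantom_spec <- function(shape, n_spheres = 8, n_rods = 4, n_shells = 2,
                         intensity = c(0.5, 1.5), sphere_radius = NULL,
                         seed = 1) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 8L)) {
    stop("`shape` must be (nz, ny, nx) with every dimension >= 8")
  }
  counts <- c(n_spheres, n_rods, n_shells)
  if (any(counts < 0)) stop("object counts must be >= 0")
  if (length(intensity) != 2L || intensity[1] <= 0 ||
      intensity[2] < intensity[1]) {
    stop("`intensity` must be c(lo, hi) with 0 < lo <= hi")
  }
  if (is.null(sphere_radius)) {
    sphere_radius <- c(3, max(3, min(shape) / 8))
  }
  if (sphere_radius[1] < 1 || sphere_radius[2] < sphere_radius[1]) {
    stop("`sphere_radius` must be c(lo, hi) with 1 <= lo <= hi")
  }
  structure(
    list(shape = shape, n_spheres = as.integer(n_spheres),
         n_rods = as.integer(n_rods), n_shells = as.integer(n_shells),
         intensity = as.numeric(intensity),
         sphere_radius = as.numeric(sphere_radius), seed = as.integer(seed)),
    class = "wf_phantom_spec"
  )
}

#' Generate a geometric phantom volume
#'
#' @param spec A [phantom_spec()].
#' @param voxel_size_A Voxel size attached to the result.
#' @return A [volume()]; zero background, deterministic for a fixed seed.
#' @export
make_phantom <- function(spec, voxel_size_A = 1) {
  stopifnot(inherits(spec, "wf_phantom_spec"))
  d <- spec$shape
  # coordinate grids, (z, y, x) order, centered
  cz <- (d[1] - 1) / 2; cy <- (d[2] - 1) / 2; cx <- (d[3] - 1) / 2
  Z <- array(seq_len(d[1]) - 1 - cz, dim = d)
  Y <- array(rep(seq_len(d[2]) - 1 - cy, each = d[1]), dim = d)
  X <- array(rep(seq_len(d[3]) - 1 - cx, each = d[1] * d[2]), dim = d)
  # placement region: cylinder about y with radius margin for rotation
  r_cyl <- 0.42 * min(d[1], d[3])
  y_half <- 0.42 * d[2]
  v <- array(0, dim = d)
  max_r <- spec$sphere_radius[2]
  with_seed(spec$seed, {
    place <- function(obj_r) {
      # center such that object of radius obj_r stays inside the margin
      repeat {
        ang <- runif(1, 0, 2 * pi)
        rad <- sqrt(runif(1)) * max(r_cyl - obj_r, 0.5)
        y0 <- runif(1, -max(y_half - obj_r, 0.5), max(y_half - obj_r, 0.5))
        return(c(x = rad * cos(ang), y = y0, z = rad * sin(ang)))
      }
    }
    rint <- function() runif(1, spec$intensity[1], spec$intensity[2])
    for (i in seq_len(spec$n_spheres)) {
      r <- runif(1, spec$sphere_radius[1], spec$sphere_radius[2])
      p <- place(r)
      v <- v + rint() * ((X - p["x"])^2 + (Y - p["y"])^2 +
                           (Z - p["z"])^2 <= r^2)
    }
    for (i in seq_len(spec$n_rods)) {
      r <- runif(1, 1.5, 3)
      len <- runif(1, 0.15, 0.3) * min(d)
      p <- place(len / 2 + r)
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      dx <- X - p["x"]; dy <- Y - p["y"]; dz <- Z - p["z"]
      t <- dx * u[1] + dy * u[2] + dz * u[3]
      perp2 <- dx^2 + dy^2 + dz^2 - t^2
      v <- v + rint() * (abs(t) <= len / 2 & perp2 <= r^2)
    }
    for (i in seq_len(spec$n_shells)) {
      r <- runif(1, max_r, 2 * max_r)
      th <- runif(1, 1.5, 2.5)
      p <- place(r + th)
      rr <- sqrt((X - p["x"])^2 + (Y - p["y"])^2 + (Z - p["z"])^2)
      v <- v + rint() * (rr >= r - th / 2 & rr <= r + th / 2)
    }
  })
  volume(v, voxel_size_A)
}

#' Project a volume into a tilt series
#'
#' Parallel-beam forward model: image k is the sum along the beam axis of
#' the volume rotated by `-alpha_k` about the tilt (y) axis, which by the
#' Fourier slice theorem measures the central Fourier slice at orientation
#' `alpha_k`.  Linear in the volume; out-of-field samples are zero.
#'
#' @param vol A [volume()] or 3D array `(nz, ny, nx)`.
#' @param scheme A [tilt_scheme()], all angles strictly inside (-90, 90).
#' @return A [tilt_series()] of `(ny, nx)` images.
#' @export
project <- function(vol, scheme) {
  if (!inherits(scheme, "wf_tilt_scheme")) {
    stop("`scheme` must be a wf_tilt_scheme")
  }
  if (any(abs(scheme$angles_deg) >= 90)) {
    stop("projection angles must lie strictly inside (-90, 90)")
  }
  v <- as_volume(vol)
  d <- dim(v$data)
  stack <- cpp_project(as.numeric(v$data), d[1], d[2], d[3],
                       scheme$angles_deg * pi / 180)
  imgs <- array(stack, dim = c(d[2], d[3], length(scheme$angles_deg)))
  tilt_series(imgs, scheme, pixel_size_A = v$voxel_size_A)
}

#' Add pixel-wise Gaussian noise at a target SNR
#'
#' SNR is defined as `Var(clean projections, pooled over the stack) /
#' Var(noise)`; the noise is i.i.d. zero-mean Gaussian.  Calling with
#' different seeds yields independent noise realizations.
#'
#' @param ts A [tilt_series()].
#' @param snr Signal-to-noise ratio (> 0).
#' @param seed Integer seed.
#' @return A [tilt_series()] with noisy images.
#' @export
add_noise <- function(ts, snr, seed = 1) {
  stopifnot(inherits(ts, "wf_tilt_series"))
  if (!is.numeric(snr) || snr <= 0) stop("`snr` must be positive")
  sd_noise <- sqrt(var(as.numeric(ts$images)) / snr)
  noisy <- with_seed(seed, {
    ts$images + array(rnorm(length(ts$images), sd = sd_noise),
                      dim = dim(ts$images))
  })
  tilt_series(noisy, ts$scheme, ts$pixel_size_A)
}

#' Simulate dose-fractionated frames for a tilt series
#'
#' Emits `frames_per_tilt` noisy frames per tilt whose average has the
#' requested SNR (per-frame noise variance is `frames_per_tilt` times the
#' per-tilt variance).
#'
#' @inheritParams add_noise
#' @param frames_per_tilt Number of frames per tilt (>= 2).
#' @return A list with one `(ny, nx, frames_per_tilt)` array per tilt.
#' @export
simulate_frames <- function(ts, snr, frames_per_tilt = 4, seed = 1) {
  stopifnot(inherits(ts, "wf_tilt_series"), frames_per_tilt >= 2)
  if (snr <= 0) stop("`snr` must be positive")
  sd_frame <- sqrt(frames_per_tilt * var(as.numeric(ts$images)) / snr)
  d <- dim(ts$images)
  with_seed(seed, {
    lapply(seq_len(d[3]), function(k) {
      clean <- ts$images[, , k]
      array(rep(clean, frames_per_tilt) +
              rnorm(length(clean) * frames_per_tilt, sd = sd_frame),
            dim = c(d[1], d[2], frames_per_tilt))
    })
  })
}
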