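# shared fixtures, all generated in code

# smooth two-blob phantom: band-limited enough for Fourier-domain checks
smooth_blob <- function(n, sigma = n / 12) {
  c0 <- (n - 1) / 2
  g <- expand.grid(z = 0:(n - 1), y = 0:(n - 1), x = 0:(n - 1))
  array(
    exp(-((g$z - c0)^2 + (g$y - c0)^2 + (g$x - c0)^2) / (2 * sigma^2)) +
      exp(-((g$z - c0 - n / 8)^2 + (g$y - c0 + n / 12)^2 +
              (g$x - c0 + n / 8)^2) / (2 * (0.75 * sigma)^2)),
    dim = rep(n, 3)
  )
}

random_volume <- function(n, seed = 1) {
  set.seed(seed)
  array(rnorm(n^3), dim = rep(n, 3))
}

# tiny training fixture: half-reconstruction pairs of side `cube` cut from
# a noisy phantom twice that size (8 non-overlapping pairs)
desk_pairs <- function(cube = 16, seed = 5, snr = 1 / 4) {
  n_side <- 2 * cube
  truth <- make_phantom(phantom_spec(rep(n_side, 3), n_spheres = 4,
                                     n_rods = 2, n_shells = 1, seed = seed))
  scheme <- make_tilt_scheme(-60, 60, 4)
  noisy <- add_noise(project(truth, scheme), snr, seed = seed + 1)
  sp <- split_even_odd(noisy)
  v0 <- fbp(sp$half0, rep(n_side, 3), "ramp")
  v1 <- fbp(sp$half1, rep(n_side, 3), "ramp")
  list(truth = truth, v0 = v0, v1 = v1,
       pairs = extract_pairs(v0, v1, plan_grid(rep(n_side, 3), cube, 0),
                             cube))
}
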