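test_that("tilt schemes enumerate angles inclusively and validate input", {
  expect_length(make_tilt_scheme(-60, 60, 3)$angles_deg, 41)
  expect_length(make_tilt_scheme(-60, 60, 2)$angles_deg, 61)
  expect_equal(make_tilt_scheme(0, 0.5, 1)$angles_deg, 0)
  expect_error(make_tilt_scheme(-60, 60, 0), "positive")
  expect_error(make_tilt_scheme(60, -60, 3), "smaller")
  expect_error(tilt_scheme(c(0, 0)), "strictly increasing")
  expect_error(tilt_scheme(c(-95, 0)), "90")
  expect_error(tilt_scheme(numeric(0)), "non-empty")
})

test_that("phantoms are deterministic, in-field, and voxelize known volumes", {
  spec <- phantom_spec(c(32, 48, 48), seed = 3)
  p1 <- make_phantom(spec)
  p2 <- make_phantom(spec)
  expect_identical(p1$data, p2$data)
  expect_true(any(p1$data > 0))
  expect_identical(min(p1$data), 0)

  empty <- make_phantom(phantom_spec(c(16, 16, 16), 0, 0, 0, seed = 1))
  expect_true(all(empty$data == 0))

  # one unit-intensity sphere of radius 5: voxel sum approximates the
  # continuous ball volume (4/3) pi 5^3 up to discretization
  one <- phantom_spec(c(48, 48, 48), n_spheres = 1, n_rods = 0,
                      n_shells = 0, intensity = c(1, 1),
                      sphere_radius = c(5, 5), seed = 9)
  vol <- make_phantom(one)
  expect_lt(abs(sum(vol$data) - 4 / 3 * pi * 5^3) / (4 / 3 * pi * 5^3),
            0.05)
  expect_error(phantom_spec(c(4, 4, 4)), ">= 8")
})

test_that("projection conserves mass and is linear", {
  n <- 32
  v <- array(0, dim = rep(n, 3))
  v[n / 2, n / 2, n / 2] <- 1
  ts <- project(volume(v), make_tilt_scheme(-60, 60, 20))
  sums <- apply(ts$images, 3, sum)
  expect_true(all(abs(sums - 1) < 0.08)) # single-voxel interpolation wobble

  blob <- smooth_blob(n)
  tsb <- project(volume(blob), make_tilt_scheme(-60, 60, 15))
  expect_true(all(abs(apply(tsb$images, 3, sum) / sum(blob) - 1) < 0.01))

  zero <- project(volume(array(0, rep(n, 3))), tilt_scheme(c(-30, 0, 30)))
  expect_true(all(zero$images == 0))

  v2 <- random_volume(n, 2)
  sch <- tilt_scheme(c(-41, 7, 33))
  lhs <- project(volume(2 * blob - 3 * v2), sch)$images
  rhs <- 2 * project(volume(blob), sch)$images -
    3 * project(volume(v2), sch)$images
  expect_lt(max(abs(lhs - rhs)), 1e-9 * max(abs(rhs)))

  expect_error(project(volume(blob), tilt_scheme(90)), "strictly inside")
})

test_that("projection agrees with the Fourier slice theorem at low freq", {
  n <- 48
  blob <- smooth_blob(n)
  a <- 30
  ar <- a * pi / 180
  P <- project(volume(blob), tilt_scheme(a))$images[, , 1]
  c0 <- (n - 1) / 2
  g <- expand.grid(z = 0:(n - 1), y = 0:(n - 1), x = 0:(n - 1))
  vv <- as.numeric(blob)
  zc <- g$z - c0; yc <- g$y - c0; xc <- g$x - c0
  pu <- rep(0:(n - 1), each = n) - c0
  py <- rep(0:(n - 1), n) - c0
  pvec <- as.numeric(P)
  err2 <- 0; ref2 <- 0
  for (ku in -6:6) {
    for (kyv in -6:6) {
      # central slice of the volume transform at orientation a (direct DFT)
      val <- sum(vv * exp(-2i * pi * ((ku * cos(ar)) * xc + kyv * yc +
                                        (-ku * sin(ar)) * zc) / n))
      pv <- sum(pvec * exp(-2i * pi * (ku * pu + kyv * py) / n))
      err2 <- err2 + Mod(pv - val)^2
      ref2 <- ref2 + Mod(val)^2
    }
  }
  expect_lt(sqrt(err2 / ref2), 0.05)
})

test_that("noise injection matches the pooled-variance SNR convention", {
  n <- 64
  blob <- smooth_blob(n)
  ts <- project(volume(blob), make_tilt_scheme(-60, 60, 1)) # 121 x 64 x 64 px
  clean_var <- var(as.numeric(ts$images))

  noisy <- add_noise(ts, snr = 1 / 4, seed = 2)
  noise <- noisy$images - ts$images
  expect_lt(abs(var(as.numeric(noise)) / (4 * clean_var) - 1), 0.05)

  # determinism and independence across seeds
  noisy2 <- add_noise(ts, snr = 1 / 4, seed = 2)
  expect_identical(noisy$images, noisy2$images)
  other <- add_noise(ts, snr = 1 / 4, seed = 3)$images - ts$images
  expect_lt(abs(cor(as.numeric(noise), as.numeric(other))), 0.01)

  # vanishing noise limit
  quiet <- add_noise(ts, snr = 1e12, seed = 1)
  expect_lt(max(abs(quiet$images - ts$images)),
            1e-4 * sd(as.numeric(ts$images)))
  expect_error(add_noise(ts, snr = 0), "positive")
})

test_that("frame simulation gives the requested SNR after averaging", {
  n <- 48
  ts <- project(volume(smooth_blob(n)), make_tilt_scheme(-40, 40, 10))
  fr <- simulate_frames(ts, snr = 1 / 2, frames_per_tilt = 4, seed = 4)
  expect_length(fr, n_tilts <- dim(ts$images)[3])
  avg <- sapply(seq_along(fr), function(k) apply(fr[[k]], c(1, 2), mean),
                simplify = "array")
  noise_var <- var(as.numeric(avg - ts$images))
  expect_lt(abs(noise_var / (2 * var(as.numeric(ts$images))) - 1), 0.1)
})
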