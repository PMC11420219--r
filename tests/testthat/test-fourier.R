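test_that("wedge masks implement the wedge inequality with measured DC", {
  shape <- c(64, 64, 64)
  wm <- wedge_mask(shape, 60)
  expect_true(all(wm$data %in% c(0, 1)))
  expect_equal(wm$data[33, 33, 33], 1) # DC voxel

  # brute-force re-evaluation of the inequality on centered indices
  kz <- wedgefill:::centered_freqs(64)
  kx <- wedgefill:::centered_freqs(64)
  t60 <- tan(60 * pi / 180)
  ref <- outer(abs(kz), abs(kx), function(az, ax) as.numeric(az <= t60 * ax))
  expect_identical(wm$data[, 17, ], ref)

  # zero fraction within the Nyquist ball equals the angular fraction 1/3
  ball <- wedgefill:::shell_index(shape) <= 30
  expect_lt(abs(mean(wm$data[ball] == 0) - 1 / 3), 0.01)

  # near-90-degrees limit: the missing wedge collapses onto the k_x = 0
  # plane (which no tilt short of 90 degrees ever measures)
  m89 <- wedge_mask(c(16, 16, 16), 89.99)$data
  kx0 <- wedgefill:::centered_freqs(16) == 0
  expect_true(all(m89[, , !kx0] == 1))
  expect_lt(mean(m89 == 0), 16 * 15 / 16^3 + 1e-12)
  expect_error(wedge_mask(shape, 0), "0, 90")
  expect_error(wedge_mask(shape, 90), "0, 90")
})

test_that("rotated wedge masks match coordinate substitution and symmetry", {
  shape <- c(32, 32, 32)
  expect_identical(rotated_wedge_mask(shape, 60, euler_angles())$data,
                   wedge_mask(shape, 60)$data)

  # 90-degree rotation about y swaps the roles of k_x and k_z
  m90 <- rotated_wedge_mask(shape, 60, euler_angles(0, pi / 2, 0))$data
  kz <- wedgefill:::centered_freqs(32)
  t60 <- tan(60 * pi / 180)
  ref <- outer(abs(kz), abs(kz), function(az, ax) as.numeric(ax <= t60 * az))
  mir <- wedgefill:::mirror_index(32)
  ref <- pmin(ref, ref[mir, mir])
  ref[17, 17] <- 1
  expect_identical(m90[, 9, ], ref)

  # zero fraction within the ball is rotation invariant; masks stay
  # point-symmetric for arbitrary rotations
  ball <- wedgefill:::shell_index(shape) <= 14
  f0 <- mean(wedge_mask(shape, 60)$data[ball] == 0)
  set.seed(11)
  for (i in 1:5) {
    m <- rotated_wedge_mask(shape, 60, sample_rotation())$data
    expect_lt(abs(mean(m[ball] == 0) - f0) / f0, 0.05)
    expect_identical(m, m[mir, mir, mir])
  }
})

test_that("apply_mask is idempotent, real, and satisfies Parseval's split", {
  n <- 24
  v <- random_volume(n, 3)
  wm <- wedge_mask(rep(n, 3), 50)

  ones <- wedgefill:::new_wedge_mask(array(1, rep(n, 3)), 89)
  expect_equal(apply_mask(v, ones), v, tolerance = 1e-10)

  mv <- apply_mask(v, wm)
  expect_equal(apply_mask(mv, wm), mv, tolerance = 1e-10)

  cv <- apply_mask(v, wedgefill:::complement_mask(wm))
  expect_equal(sum(mv^2) + sum(cv^2), sum(v^2), tolerance = 1e-8)
  expect_equal(mv + cv, v, tolerance = 1e-10)

  expect_error(apply_mask(v, wedge_mask(c(16, 16, 16), 50)), "match")
})

test_that("orthogonal mask products vanish identically", {
  n <- 16
  set.seed(4)
  M <- wedge_mask(rep(n, 3), 60)$data
  Mphi <- rotated_wedge_mask(rep(n, 3), 60, sample_rotation())$data
  expect_true(all(M * (1 - M) == 0))
  expect_true(all((M * Mphi) * ((1 - M) * Mphi) == 0))
})

test_that("sampled rotations are Haar-uniform and reproducible", {
  set.seed(99)
  ns <- 20000
  ez <- matrix(0, ns, 3)
  ct <- numeric(ns)
  for (i in seq_len(ns)) {
    phi <- sample_rotation()
    R <- euler_to_matrix(phi)
    ez[i, ] <- R[, 3]
    ct[i] <- cos(phi$theta)
  }
  # mean rotated axis is the zero vector under Haar measure
  expect_true(all(abs(colMeans(ez)) < 0.02))
  # cos(theta) of the z-y-z tilt is uniform on [-1, 1]
  ks <- stats::ks.test(ct, "punif", -1, 1)
  expect_gt(ks$p.value, 0.01)

  set.seed(7)
  a <- replicate(5, unlist(sample_rotation()))
  set.seed(7)
  b <- replicate(5, unlist(sample_rotation()))
  expect_identical(a, b)
})

test_that("volume rotation is exact for identity and lattice rotations", {
  n <- 16
  v <- random_volume(n, 5)
  out <- rotate_volume(v, euler_angles(), fill = "zero")
  expect_lt(max(abs(out - v)), 1e-6 * diff(range(v)))

  # 90-degree rotation about z permutes lattice coordinates exactly:
  # a delta at (x, y) relative to center moves to (-y, x)
  d <- array(0, dim = rep(n, 3))
  d[9, 10, 12] <- 1 # (z, y, x) 1-based
  r <- rotate_volume(d, euler_angles(pi / 2, 0, 0), fill = "zero")
  # center c = (n-1)/2 = 7.5 (0-based); (x,y) = (11,9) -> (x',y') = c - (y-c), c + (x-c)
  expect_equal(r[9, 12 - 1 + 1, 17 - 10], 1) # moved delta
  expect_equal(sum(r), 1, tolerance = 1e-9)

  # round trip of a smooth blob through a random rotation
  blob <- smooth_blob(24)
  set.seed(2)
  phi <- sample_rotation()
  Rm <- euler_to_matrix(phi)
  inv <- wedgefill:::matrix_to_euler(t(Rm))
  back <- rotate_volume(rotate_volume(blob, phi), inv)
  sh <- wedgefill:::shell_index(rep(24, 3)) # reuse as centered radius map
  inside <- sh <= 0.4 * 24
  expect_gt(cor(back[inside], blob[inside]), 0.99)

  expect_error(rotate_volume(array(0, c(4, 4, 8)), euler_angles()), "cubic")
})
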