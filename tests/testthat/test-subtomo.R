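test_that("grid planning covers the volume with clamped windows", {
  expect_identical(plan_grid(c(96, 96, 96), 96, 32), list(c(0L, 0L, 0L)))

  # stride 64 with clamping: corners {0, 64} per axis
  g <- plan_grid(c(160, 96, 96), 96, 32)
  expect_identical(sort(unique(vapply(g, `[`, integer(1), 1))), c(0L, 64L))

  # coverage count is >= 1 everywhere for assorted geometries
  for (ov in c(0, 5, 12)) {
    shape <- c(40, 33, 29)
    cube <- 16
    pos <- plan_grid(shape, cube, ov)
    cnt <- array(0L, shape)
    for (p in pos) {
      idx <- lapply(seq_len(3), function(a) p[a] + seq_len(cube))
      cnt[idx[[1]], idx[[2]], idx[[3]]] <-
        cnt[idx[[1]], idx[[2]], idx[[3]]] + 1L
    }
    expect_true(all(cnt >= 1L))
  }
  expect_error(plan_grid(c(8, 8, 8), 16, 0), "exceed")
  expect_error(plan_grid(c(32, 32, 32), 16, 16), "overlap")
})

test_that("content masks find phantom support and ignore intensity scale", {
  expect_warning(m0 <- content_mask(array(1, c(8, 8, 8))), "constant")
  expect_true(all(m0 == 0))
  expect_true(all(suppressWarnings(content_mask(array(0, c(8, 8, 8)))) == 0))

  ph <- make_phantom(phantom_spec(c(48, 48, 48), n_spheres = 5, n_rods = 0,
                                  n_shells = 0, seed = 2))
  m <- content_mask(ph, smooth_sigma = 2, percentile = 70)
  support <- ph$data > 0
  expect_gt(sum(m[support]) / sum(support), 0.95)

  m2 <- content_mask(volume(3.5 * ph$data + 11), smooth_sigma = 2,
                     percentile = 70)
  expect_identical(m, m2)
  expect_error(content_mask(ph, percentile = 0), "0, 100")
})

test_that("position filtering keeps cubes with enough sample", {
  shape <- c(16, 16, 32)
  mask <- array(0, shape)
  mask[, , 1:16] <- 1 # left half full
  pos <- list(c(0L, 0L, 0L), c(0L, 0L, 8L), c(0L, 0L, 16L))
  # fractions: 1, 0.5, 0
  expect_length(filter_positions(pos, mask, 16, 0), 3)
  expect_identical(filter_positions(pos, mask, 16, 1), pos[1])
  expect_identical(filter_positions(pos, mask, 16, 0.4), pos[1:2])
  # brute-force check of the kept fractions
  fr <- vapply(pos, function(p) {
    mean(mask[p[1] + 1:16, p[2] + 1:16, p[3] + 1:16])
  }, numeric(1))
  expect_identical(filter_positions(pos, mask, 16, 0.4), pos[fr >= 0.4])
})

test_that("pair extraction copies cubes and records statistics", {
  v <- random_volume(24, 7)
  pos <- plan_grid(rep(24, 3), 8, 0)
  pairs <- extract_pairs(v, v, pos, 8)
  expect_length(pairs, length(pos))
  for (pr in pairs[c(1, 5, length(pairs))]) {
    expect_identical(pr$v0, pr$v1)
    expect_equal(unname(pr$norm_stats["mean"]), mean(pr$v0))
    expect_equal(unname(pr$norm_stats["sd"]), sd(as.numeric(pr$v0)))
  }
  again <- extract_pairs(v, v, pos, 8)
  expect_identical(pairs, again)
  expect_error(extract_pairs(v, v, list(c(0L, 0L, 20L)), 8), "out of bounds")
  expect_error(extract_pairs(array(0, rep(8, 3)), array(0, rep(8, 3)),
                             list(c(0L, 0L, 0L)), 8), "sd = 0")
})

test_that("extract -> reassemble is the identity for any valid overlap", {
  v <- random_volume(24, 8)
  for (ov in c(0, 3, 6)) {
    pos <- plan_grid(rep(24, 3), 12, ov)
    cubes <- lapply(pos, function(p) wedgefill:::extract_cube(v, p, 12))
    expect_equal(reassemble(cubes, pos, rep(24, 3)), v, tolerance = 1e-12)
  }
})

test_that("reassembly averages overlapping cubes uniformly", {
  pos <- list(c(0L, 0L, 0L), c(0L, 0L, 4L))
  cubes <- list(array(0, rep(8, 3)), array(2, rep(8, 3)))
  out <- reassemble(cubes, pos, c(8, 8, 12))
  expect_true(all(out[, , 1:4] == 0))
  expect_true(all(out[, , 5:8] == 1))
  expect_true(all(out[, , 9:12] == 2))

  # probe voxel equals the brute-force mean over covering cubes
  set.seed(1)
  pos2 <- plan_grid(c(16, 16, 16), 8, 4)
  cubes2 <- lapply(pos2, function(p) array(rnorm(512), rep(8, 3)))
  out2 <- reassemble(cubes2, pos2, rep(16, 3))
  probe <- c(8L, 8L, 8L) # 1-based voxel
  vals <- c()
  for (i in seq_along(pos2)) {
    p <- pos2[[i]]
    rel <- probe - p
    if (all(rel >= 1 & rel <= 8)) {
      vals <- c(vals, cubes2[[i]][rel[1], rel[2], rel[3]])
    }
  }
  expect_equal(out2[probe[1], probe[2], probe[3]], mean(vals))

  expect_error(reassemble(cubes, pos, c(8, 8, 20)), "cover")
})
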