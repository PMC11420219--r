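test_that("epoch samples pair masked rotated inputs with rotated targets", {
  fx <- desk_pairs(16, seed = 21)
  pairs <- fx$pairs
  mask <- wedge_mask(rep(16, 3), 60)

  # all-ones mask and identity rotation reduce to the raw pair
  ones <- wedgefill:::new_wedge_mask(array(1, rep(16, 3)), 89)
  s0 <- testthat::with_mocked_bindings(
    make_epoch_samples(pairs[1], ones, rotation_fill = "zero"),
    sample_rotation = function() euler_angles(), .package = "wedgefill"
  )
  expect_equal(s0[[1]]$input, pairs[[1]]$v0, tolerance = 1e-6)
  expect_equal(s0[[1]]$target, pairs[[1]]$v1, tolerance = 1e-6)

  # the input's Fourier energy inside the wedge is numerically zero
  set.seed(31)
  s <- make_epoch_samples(pairs, mask)[[1]]
  Fi <- wedgefill:::fftshift3(wedgefill:::fft_u(s$input))
  frac <- sum(Mod(Fi[mask$data == 0])^2) / sum(Mod(Fi)^2)
  expect_lt(frac, 1e-10)

  # fresh rotations on every call
  set.seed(32)
  a <- make_epoch_samples(pairs, mask)
  b <- make_epoch_samples(pairs, mask)
  expect_false(identical(a[[1]]$phi, b[[1]]$phi))
})

test_that("per-sample loss matches a dense-DFT brute-force evaluation", {
  n <- 8
  set.seed(41)
  pred <- array(rnorm(n^3), rep(n, 3))
  target <- array(rnorm(n^3), rep(n, 3))
  M <- wedge_mask(rep(n, 3), 60)
  Mphi <- rotated_wedge_mask(rep(n, 3), 60, sample_rotation())

  got <- per_sample_loss(pred, target, M, Mphi)

  # independent oracle: explicit unitary DFT matrix (Kronecker of 1D DFTs)
  F1 <- outer(0:(n - 1), 0:(n - 1),
              function(j, k) exp(-2i * pi * j * k / n)) / sqrt(n)
  F3 <- kronecker(F1, kronecker(F1, F1)) # acts on (z fastest) vectorization
  d <- as.numeric(pred - target)
  Fd <- F3 %*% d
  w <- as.numeric(wedgefill:::ifftshift3(M$data * Mphi$data +
                                           2 * (1 - M$data) * Mphi$data))
  ref <- sum(Mod(w * Fd)^2)
  expect_lt(abs(got - ref) / ref, 1e-6)

  # reductions: equal volumes give zero; all-ones masks give image-domain MSE
  expect_equal(per_sample_loss(pred, pred, M, Mphi), 0)
  ones <- wedgefill:::new_wedge_mask(array(1, rep(n, 3)), 89)
  expect_equal(per_sample_loss(pred, target, ones, ones),
               sum((pred - target)^2), tolerance = 1e-8)
  expect_error(per_sample_loss(pred, array(0, rep(4, 3)), M, Mphi), "match")
})

test_that("the loss splits into orthogonal Noise2Noise and wedge terms", {
  n <- 8
  set.seed(42)
  pred <- array(rnorm(n^3), rep(n, 3))
  target <- array(rnorm(n^3), rep(n, 3))
  M <- wedge_mask(rep(n, 3), 60)
  Mphi <- rotated_wedge_mask(rep(n, 3), 60, sample_rotation())
  Fd <- wedgefill:::fft_u(pred - target)
  m <- wedgefill:::ifftshift3(M$data)
  mp <- wedgefill:::ifftshift3(Mphi$data)
  n2n <- sum(Mod(m * mp * Fd)^2)
  wedge <- sum(Mod(2 * (1 - m) * mp * Fd)^2)
  expect_true(all((m * mp) * ((1 - m) * mp) == 0))
  expect_equal(per_sample_loss(pred, target, M, Mphi), n2n + wedge,
               tolerance = 1e-10)
})

test_that("wedge updates preserve the measured region and skip v1", {
  fx <- desk_pairs(16, seed = 51)
  pairs <- wedgefill:::standardize_pairs(fx$pairs)
  mask <- wedge_mask(rep(16, 3), 60)

  ident <- update_wedges(pairs, identity, mask)
  expect_equal(ident[[1]]$v0, pairs[[1]]$v0, tolerance = 1e-10)

  zero_model <- function(x) array(0, dim = dim(x))
  zeroed <- update_wedges(pairs, zero_model, mask)
  expect_equal(zeroed[[1]]$v0, apply_mask(pairs[[1]]$v0, mask),
               tolerance = 1e-10)

  net <- build_unet(unet_config_desk(), seed = 1)
  upd <- update_wedges(pairs, net, mask)
  for (i in seq_along(pairs)) {
    dF <- wedgefill:::fftshift3(
      wedgefill:::fft_u(upd[[i]]$v0 - pairs[[i]]$v0)
    )
    inside_meas <- sqrt(sum(Mod(dF[mask$data == 1])^2))
    expect_lt(inside_meas, 1e-6 * sqrt(sum(pairs[[i]]$v0^2)))
    expect_identical(upd[[i]]$v1, pairs[[i]]$v1)
  }
})

test_that("fitting is deterministic, gated by wedge_update, and learns", {
  fx <- desk_pairs(16, seed = 61)
  pairs <- fx$pairs

  base_cfg <- function(...) {
    args <- utils::modifyList(
      list(cube_size = 16, epochs = 2, batch_size = 4, seed = 9,
           unet = unet_config(base_channels = 4, depth = 2)),
      list(...)
    )
    do.call(fit_config, args)
  }

  # zero learning rate: model stays at its initialization
  r0 <- fit(pairs, base_cfg(learning_rate = 0, epochs = 1,
                            wedge_update = FALSE))
  expect_equal(nrow(r0$history), 1)
  # same seed, same history
  r1 <- fit(pairs, base_cfg())
  r2 <- fit(pairs, base_cfg())
  expect_identical(r1$history$loss, r2$history$loss)
  expect_identical(r1$model$params, r2$model$params)

  # learning: the fitted model beats its own initialization on a common,
  # fixed evaluation set (per-epoch losses are too noisy on 8 pairs since
  # every epoch redraws the rotations)
  cfg <- fit_config(cube_size = 16, epochs = 12, batch_size = 4, seed = 3,
                    unet = unet_config(base_channels = 8, depth = 2))
  res <- fit(pairs, cfg)
  init <- wedgefill:::with_seed(cfg$seed, {
    build_unet(cfg$unet, seed = sample.int(.Machine$integer.max, 1))
  })
  mask16 <- wedge_mask(rep(16, 3), cfg$alpha_max_deg)
  spairs <- wedgefill:::standardize_pairs(pairs)
  set.seed(1234)
  evalset <- make_epoch_samples(spairs, mask16)
  mean_loss <- function(model) {
    mean(vapply(evalset, function(s) {
      mphi <- rotated_wedge_mask(rep(16, 3), cfg$alpha_max_deg, s$phi)
      per_sample_loss(unet_predict(model, s$input), s$target, mask16, mphi)
    }, numeric(1)))
  }
  # at this noise level (SNR 1/4, tiny cubes) the attainable optimum is
  # close to the best constant predictor; fitting must improve on the
  # random initialization and land at (or below) that floor
  floor0 <- mean_loss(function(x) array(0, dim = dim(x)))
  expect_lt(mean_loss(res$model), mean_loss(init))
  expect_lt(mean_loss(res$model), 1.05 * floor0)

  # validation losses are recorded when requested
  rv <- fit(pairs, fit_config(cube_size = 16, epochs = 1, batch_size = 4,
                              seed = 2, val_fraction = 0.25,
                              unet = unet_config(4, 2)))
  expect_true("val_loss" %in% names(rv$history))
  expect_true(is.finite(rv$history$val_loss[1]))

  expect_error(fit(list(), base_cfg()), "at least one")
  expect_error(fit(pairs, fit_config(cube_size = 32,
                                     unet = unet_config(4, 2))), "cubic")
})

test_that("zero-learning-rate fit returns the seed-matched initialization", {
  fx <- desk_pairs(16, seed = 71)
  cfg <- fit_config(cube_size = 16, epochs = 1, learning_rate = 0,
                    batch_size = 4, seed = 5, wedge_update = FALSE,
                    unet = unet_config(4, 2))
  res <- fit(fx$pairs, cfg)
  # rebuild the initialization from the same fanned-out seed
  ref <- wedgefill:::with_seed(5, {
    build_unet(cfg$unet, seed = sample.int(.Machine$integer.max, 1))
  })
  expect_identical(res$model$params, ref$params)
})
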