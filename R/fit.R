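#' Fit configuration
#'
#' Hyperparameters of the self-supervised fitting loop.  Defaults follow
#' the reference setup: Adam with a constant learning rate of `4e-4`, no
#' dropout, one full pass over the sub-tomogram pairs per epoch, and a
#' wedge update of the model inputs after every epoch.
#'
#' @param alpha_max_deg Maximal tilt angle defining the missing wedge.
#' @param cube_size Sub-tomogram side (divisible by `2^depth`).
#' @param epochs Number of epochs (>= 1).
#' @param batch_size Mini-batch size (default 8).
#' @param learning_rate Adam learning rate (default `4e-4`).
#' @param seed Seed fanning out to initialization, rotation sampling and
#'   batch shuffling.
#' @param wedge_update Refill the missing wedges of the model inputs with
#'   the current model after each epoch (default `TRUE`).
#' @param rotation_fill Fill rule for out-of-cube samples when rotating
#'   (`"mean"` or `"zero"`).
#' @param unet A [unet_config()] for the fitted network.
#' @param val_fraction Fraction of pairs held out for a validation loss
#'   (0 disables validation).
#' @return An object of class `wf_fit_config`.
#' @export
fit_config <- function(alpha_max_deg = 60, cube_size = 32, epochs = 30,
                       batch_size = 8, learning_rate = 4e-4, seed = 0,
                       wedge_update = TRUE,
                       rotation_fill = c("mean", "zero"),
                       unet = unet_config(), val_fraction = 0) {
  if (learning_rate < 0) stop("`learning_rate` must be non-negative")
  if (epochs < 1) stop("`epochs` must be >= 1")
  if (batch_size < 1) stop("`batch_size` must be >= 1")
  if (val_fraction < 0 || val_fraction >= 1) {
    stop("`val_fraction` must lie in [0, 1)")
  }
  check_alpha(alpha_max_deg)
  structure(
    list(alpha_max_deg = alpha_max_deg, cube_size = as.integer(cube_size),
         epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         learning_rate = learning_rate, seed = as.integer(seed),
         wedge_update = isTRUE(wedge_update),
         rotation_fill = match.arg(rotation_fill),
         unet = unet, val_fraction = val_fraction),
    class = "wf_fit_config"
  )
}

#' Generate one epoch of model inputs and targets
#'
#' For each pair, draws a Haar-uniform rotation `phi_i`, rotates both
#' sub-tomograms, and adds the artificial missing wedge to the rotated
#' half-0 cube: `input_i = F^-1 M F R(v0_i)`, `target_i = R(v1_i)`.
#' Rotations are drawn from R's global RNG, so successive calls give fresh
#' rotations.
#'
#' @param pairs List of `wf_subtomo_pair` (cubic).
#' @param mask The axis-aligned [wedge_mask()] `M`.
#' @param rotation_fill Fill rule passed to [rotate_volume()].
#' @return List of `list(input, target, phi)` triplets.
#' @export
make_epoch_samples <- function(pairs, mask, rotation_fill = "mean") {
  lapply(pairs, function(pr) {
    phi <- sample_rotation()
    v0r <- rotate_volume(pr$v0, phi, fill = rotation_fill)
    v1r <- rotate_volume(pr$v1, phi, fill = rotation_fill)
    list(input = apply_mask(v0r, mask), target = v1r, phi = phi)
  })
}

# squared-weight field of the per-sample loss, natural fft order:
# w = M Mphi + 2 M^C Mphi  ->  w^2 = M Mphi + 4 M^C Mphi
loss_weight_sq <- function(mask, mask_phi) {
  m <- mask$data
  mp <- mask_phi$data
  ifftshift3(m * mp + 4 * (1 - m) * mp)
}

#' Per-sample fitting loss
#'
#' The squared L2 norm of `(M M_phi + 2 M^C M_phi) F (pred - target)`
#' computed with the unitary Fourier transform, i.e. the Noise2Noise term
#' on frequencies measured in both input and target plus the 4x-weighted
#' Noisier2Noise term on the artificially removed wedge.
#'
#' @param pred,target Cubic 3D arrays (or [volume()]s) of the same shape.
#' @param mask The axis-aligned [wedge_mask()] `M`.
#' @param mask_phi The rotated mask `M_phi` for this sample.
#' @return Non-negative scalar loss.
#' @export
per_sample_loss <- function(pred, target, mask, mask_phi) {
  if (!identical(dim(vol_data(pred)), dim(vol_data(target)))) {
    stop("`pred` and `target` shapes must match")
  }
  d <- vol_data(pred) - vol_data(target)
  Fd <- fft_u(d)
  m <- ifftshift3(mask$data)
  mp <- ifftshift3(mask_phi$data)
  w <- m * mp + 2 * (1 - m) * mp
  sum(Mod(w * Fd)^2)
}

# loss and its gradient wrt pred (both in one pass)
loss_and_grad <- function(pred, target, w_sq) {
  d <- pred - target
  Fd <- fft_u(d)
  wFd <- w_sq * Fd
  loss <- sum(Re(Conj(Fd) * wFd))
  grad <- 2 * Re(ifft_u(wFd))
  list(loss = loss, grad = grad)
}

#' Refill the missing wedges of the half-0 sub-tomograms
#'
#' Implements the wedge update: `v0 <- F^-1 (M F v0 + M^C F f(v0))`.  The
#' measured region (support of `M`) is preserved; only the wedge content is
#' replaced by the model prediction.  The half-1 cubes are never touched.
#'
#' @param pairs List of `wf_subtomo_pair`.
#' @param model A `wf_unet` (run in inference mode) or a function.
#' @param mask The axis-aligned [wedge_mask()] `M`.
#' @return The updated list of pairs.
#' @export
update_wedges <- function(pairs, model, mask) {
  m <- ifftshift3(mask$data)
  lapply(pairs, function(pr) {
    pred <- unet_predict(model, pr$v0)
    pr$v0 <- Re(ifft_u(m * fft_u(pr$v0) + (1 - m) * fft_u(pred)))
    pr
  })
}

# Adam update; state is a list of moment pairs matching the params
adam_step <- function(params, grads, state, lr, t, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  for (nm in names(params)) {
    for (f in c("W", "b")) {
      g <- grads[[nm]][[f]]
      state[[nm]][[f]]$m <- beta1 * state[[nm]][[f]]$m + (1 - beta1) * g
      state[[nm]][[f]]$v <- beta2 * state[[nm]][[f]]$v + (1 - beta2) * g^2
      mhat <- state[[nm]][[f]]$m / (1 - beta1^t)
      vhat <- state[[nm]][[f]]$v / (1 - beta2^t)
      params[[nm]][[f]] <- params[[nm]][[f]] -
        lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(params = params, state = state)
}

adam_init <- function(params) {
  lapply(params, function(l) {
    lapply(l, function(x) list(m = 0 * x, v = 0 * x))
  })
}

# standardize the pair cubes with the half-0 statistics
standardize_pairs <- function(pairs) {
  lapply(pairs, function(pr) {
    pr$v0 <- (pr$v0 - pr$norm_stats["mean"]) / pr$norm_stats["sd"]
    pr$v1 <- (pr$v1 - pr$norm_stats["mean"]) / pr$norm_stats["sd"]
    pr
  })
}

#' Fit the network on sub-tomogram pairs
#'
#' One epoch consists of: fresh Haar-uniform rotations and artificial-wedge
#' corruption for every pair ([make_epoch_samples()]), a single Adam pass
#' over the resulting input/target set in shuffled mini-batches under the
#' masked Fourier loss ([per_sample_loss()]), and, if enabled, a wedge
#' update of the model inputs ([update_wedges()]).  All cubes are
#' standardized with their half-0 statistics before fitting.  Deterministic
#' for a fixed `cfg$seed`.
#'
#' @param pairs List of `wf_subtomo_pair` with cubic cubes of side
#'   `cfg$cube_size`.
#' @param cfg A [fit_config()].
#' @param verbose Print the per-epoch loss.
#' @return A list with `model` (the fitted `wf_unet`) and `history` (data
#'   frame with one row per epoch: `epoch`, `loss`, optionally `val_loss`).
#' @export
fit <- function(pairs, cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "wf_fit_config"))
  if (length(pairs) < 1L) stop("need at least one sub-tomogram pair")
  sides <- vapply(pairs, function(pr) dim(pr$v0)[1], numeric(1))
  if (any(sides != cfg$cube_size) ||
      any(vapply(pairs, function(pr) length(unique(dim(pr$v0))) != 1L,
                 logical(1)))) {
    stop("all pairs must be cubic with side `cfg$cube_size`")
  }
  cube <- cfg$cube_size
  mask <- wedge_mask(rep(cube, 3), cfg$alpha_max_deg)
  spairs <- standardize_pairs(pairs)

  n_val <- floor(cfg$val_fraction * length(spairs))
  val_idx <- integer(0)
  with_seed(cfg$seed, {
    if (n_val > 0) {
      val_idx <- sample(seq_along(spairs), n_val)
    }
    train_idx <- setdiff(seq_along(spairs), val_idx)
    if (length(train_idx) == 0L) stop("no training pairs left")
    model <- build_unet(cfg$unet, seed = sample.int(.Machine$integer.max, 1))
    state <- adam_init(model$params)
    t_step <- 0L
    history <- data.frame(epoch = integer(0), loss = numeric(0))
    if (n_val > 0) history$val_loss <- numeric(0)

    for (ep in seq_len(cfg$epochs)) {
      samples <- make_epoch_samples(spairs[train_idx], mask,
                                    cfg$rotation_fill)
      ord <- sample(length(samples))
      ep_loss <- 0
      nb <- ceiling(length(ord) / cfg$batch_size)
      for (b in seq_len(nb)) {
        idx <- ord[((b - 1) * cfg$batch_size + 1):
                     min(b * cfg$batch_size, length(ord))]
        gacc <- NULL
        for (i in idx) {
          s <- samples[[i]]
          fw <- unet_forward(model, s$input, train = TRUE,
                             keep_cache = TRUE)
          mphi <- rotated_wedge_mask(rep(cube, 3), cfg$alpha_max_deg,
                                     s$phi)
          lg <- loss_and_grad(fw$pred, s$target,
                              loss_weight_sq(mask, mphi))
          ep_loss <- ep_loss + lg$loss
          g <- unet_backward(model, fw$cache, lg$grad)
          gacc <- if (is.null(gacc)) g else {
            mapply(function(a, b) list(W = a$W + b$W, b = a$b + b$b),
                   gacc, g, SIMPLIFY = FALSE)
          }
        }
        gacc <- lapply(gacc, function(l) list(W = l$W / length(idx),
                                              b = l$b / length(idx)))
        t_step <- t_step + 1L
        up <- adam_step(model$params, gacc, state, cfg$learning_rate,
                        t_step)
        model$params <- up$params
        state <- up$state
      }
      rec <- data.frame(epoch = ep, loss = ep_loss / length(train_idx))
      if (n_val > 0) {
        vl <- 0
        vsamples <- make_epoch_samples(spairs[val_idx], mask,
                                       cfg$rotation_fill)
        for (s in vsamples) {
          pred <- unet_forward(model, s$input)
          mphi <- rotated_wedge_mask(rep(cube, 3), cfg$alpha_max_deg,
                                     s$phi)
          vl <- vl + per_sample_loss(pred, s$target, mask, mphi)
        }
        rec$val_loss <- vl / n_val
      }
      history <- rbind(history, rec)
      if (verbose) {
        cat(sprintf("epoch %d: loss %.6g\n", ep, rec$loss))
      }
      if (cfg$wedge_update) {
        spairs[train_idx] <- update_wedges(spairs[train_idx], model, mask)
      }
    }
    list(model = model, history = history)
  })
}
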