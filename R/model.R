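#' @name model
#' @title Volumetric U-Net
#'
#' @description
#' The denoiser/inpainter is a 3D U-Net with channel doubling per
#' resolution level.  The block layout is frozen here:
#'
#' * encoder: `depth` levels with two 3x3x3 conv + ReLU layers each
#'   (channels `base * 2^n`), followed by 2x max-pooling;
#' * bottleneck: three convs, `c -> 2c -> 2c -> c` with `c = base *
#'   2^(depth-1)`;
#' * decoder: nearest-neighbour 2x upsampling, concatenation with the skip
#'   connection, then three conv + ReLU layers per level (two at the finest
#'   level);
#' * output: a 1x1x1 convolution to one channel.
#'
#' There are no normalization layers (inputs are standardized per cube);
#' optional dropout after every hidden ReLU.  With the default
#' `base_channels = 64` and `depth = 3` the network has 27.3 million
#' trainable parameters.
NULL

#' U-Net configuration
#'
#' @param base_channels First-level channel count (default 64).
#' @param depth Number of downsampling levels (default 3); input cube sides
#'   must be divisible by `2^depth`.
#' @param dropout_p Dropout probability in `[0, 1)` after hidden ReLUs
#'   (default 0).
#' @param in_channels,out_channels Input/output channels (1 for volumes).
#' @return An object of class `wf_unet_config`.
#' @export
unet_config <- function(base_channels = 64, depth = 3, dropout_p = 0,
                        in_channels = 1, out_channels = 1) {
  if (base_channels < 1 || depth < 1) {
    stop("`base_channels` and `depth` must be >= 1")
  }
  if (dropout_p < 0 || dropout_p >= 1) stop("`dropout_p` must be in [0, 1)")
  structure(
    list(base_channels = as.integer(base_channels), depth = as.integer(depth),
         dropout_p = dropout_p, in_channels = as.integer(in_channels),
         out_channels = as.integer(out_channels)),
    class = "wf_unet_config"
  )
}

#' Desk-scale U-Net preset
#'
#' A small configuration (16 first-level channels, two downsampling
#' levels, ~0.4 M parameters) for CPU-scale runs and tests; the full-scale
#' default is [unet_config()].
#'
#' @inheritParams unet_config
#' @return A [unet_config()] object.
#' @export
unet_config_desk <- function(dropout_p = 0) {
  unet_config(base_channels = 16, depth = 2, dropout_p = dropout_p)
}

# ordered list of conv layer shapes (in, out, kernel) implied by the layout
unet_layer_plan <- function(cfg) {
  b <- cfg$base_channels
  d <- cfg$depth
  plan <- list()
  add <- function(name, cin, cout, kernel = 3L) {
    plan[[name]] <<- list(cin = as.integer(cin), cout = as.integer(cout),
                          kernel = as.integer(kernel))
  }
  cin <- cfg$in_channels
  for (n in seq_len(d) - 1L) {
    ch <- b * 2^n
    add(sprintf("enc%d_1", n), cin, ch)
    add(sprintf("enc%d_2", n), ch, ch)
    cin <- ch
  }
  cb <- b * 2^d
  add("bott_1", cin, cb)
  add("bott_2", cb, cb)
  add("bott_3", cb, cb / 2)
  cin <- cb / 2
  for (n in rev(seq_len(d) - 1L)) {
    ch <- b * 2^n
    cat_in <- cin + ch
    ncv <- if (n > 0L) 3L else 2L
    add(sprintf("dec%d_1", n), cat_in, ch)
    if (ncv >= 2L) add(sprintf("dec%d_2", n), ch, ch)
    if (ncv >= 3L) add(sprintf("dec%d_3", n), ch, ch)
    cin <- ch
  }
  add("final", cin, cfg$out_channels, kernel = 1L)
  plan
}

#' Build a 3D U-Net
#'
#' Weights are He-initialized (kernel entries `N(0, 2 / fan_in)`, zero
#' biases); initialization is deterministic for a fixed seed.
#'
#' @param cfg A [unet_config()].
#' @param seed Integer seed for the weight initialization.
#' @return An object of class `wf_unet` with fields `cfg` and `params`.
#' @export
build_unet <- function(cfg = unet_config(), seed = 0) {
  stopifnot(inherits(cfg, "wf_unet_config"))
  plan <- unet_layer_plan(cfg)
  params <- with_seed(seed, {
    lapply(plan, function(l) {
      k3 <- l$kernel^3
      fan_in <- l$cin * k3
      W <- matrix(rnorm(k3 * l$cin * l$cout, sd = sqrt(2 / fan_in)),
                  nrow = k3 * l$cin, ncol = l$cout)
      list(W = W, b = rep(0, l$cout))
    })
  })
  structure(list(cfg = cfg, params = params), class = "wf_unet")
}

#' Count trainable parameters
#'
#' @param model A `wf_unet`, or any nested list of numeric arrays.
#' @return Total number of trainable scalar parameters.
#' @export
count_params <- function(model) {
  if (inherits(model, "wf_unet")) model <- model$params
  if (is.numeric(model)) return(length(model))
  sum(vapply(model, count_params, numeric(1)))
}

#' @export
print.wf_unet <- function(x, ...) {
  cat(sprintf(
    "<wf_unet base %d, depth %d, dropout %.2g: %s trainable parameters>\n",
    x$cfg$base_channels, x$cfg$depth, x$cfg$dropout_p,
    format(count_params(x), big.mark = ",")
  ))
  invisible(x)
}

# forward pass on one cube; returns prediction and (optionally) the cache
# needed for backprop.  `x` is a cubic 3D array with side divisible by
# 2^depth.  Activations live in C++ as single-precision matrices behind
# external pointers (see src/ops.cpp).
unet_forward <- function(model, x, train = FALSE, keep_cache = FALSE) {
  cfg <- model$cfg
  p <- model$params
  side <- dim(x)[1]
  if (length(unique(dim(x))) != 1L) stop("input cube must be cubic")
  if (side %% 2^cfg$depth != 0) {
    stop("cube side must be divisible by 2^depth")
  }
  drop_p <- if (train) cfg$dropout_p else 0
  cache <- list()
  act <- function(name, A, dims) {
    # conv -> ReLU (-> dropout); records what backprop needs
    out <- nn_conv(A, dims[1], dims[2], dims[3], p[[name]]$W, p[[name]]$b,
                   TRUE)
    st <- list(A = A, out = out, dims = dims)
    if (drop_p > 0) {
      dr <- nn_dropout(out, drop_p)
      out <- dr$out
      st$keep <- dr$mask
    }
    if (keep_cache) cache[[name]] <<- st
    out
  }
  dims <- rep(side, 3L)
  A <- nn_from_vol(as.numeric(x), dims[1], dims[2], dims[3])
  skips <- list()
  for (n in seq_len(cfg$depth) - 1L) {
    A <- act(sprintf("enc%d_1", n), A, dims)
    A <- act(sprintf("enc%d_2", n), A, dims)
    skips[[n + 1L]] <- A
    pl <- nn_pool(A, dims[1], dims[2], dims[3])
    if (keep_cache) cache[[sprintf("pool%d", n)]] <- list(arg = pl$arg,
                                                          dims = dims)
    A <- pl$out
    dims <- dims %/% 2L
  }
  A <- act("bott_1", A, dims)
  A <- act("bott_2", A, dims)
  A <- act("bott_3", A, dims)
  for (n in rev(seq_len(cfg$depth) - 1L)) {
    A <- nn_upsample(A, dims[1], dims[2], dims[3])
    if (keep_cache) cache[[sprintf("up%d", n)]] <- list(dims = dims)
    dims <- dims * 2L
    nch_up <- nn_ncols(A)
    A <- nn_concat(A, skips[[n + 1L]])
    if (keep_cache) cache[[sprintf("cat%d", n)]] <- list(nch_up = nch_up)
    A <- act(sprintf("dec%d_1", n), A, dims)
    A <- act(sprintf("dec%d_2", n), A, dims)
    if (!is.null(p[[sprintf("dec%d_3", n)]])) {
      A <- act(sprintf("dec%d_3", n), A, dims)
    }
  }
  if (keep_cache) cache[["final"]] <- list(A = A, dims = dims)
  out <- nn_conv1(A, dims[1], dims[2], dims[3], p[["final"]]$W,
                  p[["final"]]$b)
  pred <- array(nn_to_vol(out, dims[1], dims[2], dims[3], 0L),
                dim = rep(side, 3))
  if (keep_cache) list(pred = pred, cache = cache) else pred
}

# backward pass: dpred is the gradient of the loss wrt the prediction (3D
# array).  Returns gradients with the same structure as model$params.
unet_backward <- function(model, cache, dpred) {
  cfg <- model$cfg
  p <- model$params
  grads <- lapply(p, function(l) list(W = 0 * l$W, b = 0 * l$b))
  side <- dim(dpred)[1]
  dims <- rep(side, 3L)
  G <- nn_from_vol(as.numeric(dpred), dims[1], dims[2], dims[3])
  # final 1x1x1 layer
  st <- cache[["final"]]
  r <- nn_conv1_bwd(st$A, dims[1], dims[2], dims[3], p[["final"]]$W, G)
  grads[["final"]]$W <- r$dW
  grads[["final"]]$b <- as.numeric(r$db)
  G <- r$dA
  bwd_act <- function(name, G) {
    st <- cache[[name]]
    if (!is.null(st$keep)) G <- nn_mul(G, st$keep)
    r <- nn_conv_bwd(st$A, st$out, st$dims[1], st$dims[2], st$dims[3],
                     p[[name]]$W, G, TRUE)
    grads[[name]]$W <<- r$dW
    grads[[name]]$b <<- as.numeric(r$db)
    r$dA
  }
  for (n in seq_len(cfg$depth) - 1L) {
    if (!is.null(p[[sprintf("dec%d_3", n)]])) {
      G <- bwd_act(sprintf("dec%d_3", n), G)
    }
    G <- bwd_act(sprintf("dec%d_2", n), G)
    G <- bwd_act(sprintf("dec%d_1", n), G)
    nch_up <- cache[[sprintf("cat%d", n)]]$nch_up
    nch <- nn_ncols(G)
    G_skip <- nn_cols(G, nch_up, nch - 1L)
    G_up <- nn_cols(G, 0L, nch_up - 1L)
    dims_lo <- cache[[sprintf("up%d", n)]]$dims
    G <- nn_upsample_bwd(G_up, dims_lo[1], dims_lo[2], dims_lo[3])
    # stash the skip gradient for the encoder sweep
    cache[[sprintf("skipgrad%d", n)]] <- G_skip
  }
  G <- bwd_act("bott_3", G)
  G <- bwd_act("bott_2", G)
  G <- bwd_act("bott_1", G)
  for (n in rev(seq_len(cfg$depth) - 1L)) {
    pl <- cache[[sprintf("pool%d", n)]]
    G <- nn_pool_bwd(G, pl$arg, pl$dims[1], pl$dims[2], pl$dims[3])
    G <- nn_add(G, cache[[sprintf("skipgrad%d", n)]])
    G <- bwd_act(sprintf("enc%d_2", n), G)
    G <- bwd_act(sprintf("enc%d_1", n), G)
  }
  grads
}

#' Apply a model to a cubic volume
#'
#' Runs the network in inference mode (no dropout).  `model` may also be a
#' plain R function mapping an array to an array, which is convenient for
#' testing.
#'
#' @param model A `wf_unet` or a function.
#' @param x Cubic 3D array.
#' @return 3D array of the same shape.
#' @export
unet_predict <- function(model, x) {
  if (is.function(model)) return(model(x))
  unet_forward(model, x, train = FALSE, keep_cache = FALSE)
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the network configuration (and optionally the fit
#' configuration) for reproducibility.
#'
#' @param model A `wf_unet`.
#' @param path Destination path.
#' @param fit_config Optional [fit_config()] to embed.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path, fit_config = NULL) {
  saveRDS(list(model = model, fit_config = fit_config), path)
  invisible(path)
}

#' @rdname save_model
#' @return `load_model()`: a list with `model` and `fit_config`.
#' @export
load_model <- function(path) {
  readRDS(path)
}
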