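#' Run the full reconstruction pipeline
#'
#' Chains the three algorithm steps: split the tilt series (or take
#' pre-reconstructed even/odd volumes), reconstruct both halves with
#' filtered back-projection, extract sub-tomogram pairs, fit the network
#' with the self-supervised masked loss, refine, and (when a ground-truth
#' volume is given) evaluate.  All intermediate artifacts, the effective
#' configuration and the per-epoch loss log are written to the run
#' directory.
#'
#' @param config A named list (or path to a YAML file) with entries:
#'   * `tilt_series`, `angles`: MRC stack and .tlt file, or
#'   * `even`, `odd`: MRC volumes of the two halves;
#'   * `out_dir`: run directory (required);
#'   * `alpha_max_deg` (60), `cube_size` (32), `overlap` (cube/2),
#'     `epochs` (30), `batch_size` (4), `learning_rate` (4e-4),
#'     `base_channels` (16), `depth` (2), `dropout_p` (0), `seed` (0),
#'     `filter` ("ramp"), `nz` (z-extent of the FBP volume, required for
#'     tilt-series input), `min_fraction` (0: no content filtering),
#'     `truth`: optional ground-truth MRC for evaluation.
#' @return Invisibly, a list with the refined [volume()], fit history and
#'   (optionally) a metrics data frame.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- config
  default <- function(name, val) if (is.null(cfg[[name]])) val else cfg[[name]]
  if (is.null(cfg$out_dir)) stop("config must name an `out_dir`")
  if (!is.null(cfg$epochs) && cfg$epochs < 1) stop("`epochs` must be >= 1")
  alpha <- default("alpha_max_deg", 60)
  cube <- default("cube_size", 32)
  overlap <- default("overlap", cube %/% 2)
  epochs <- default("epochs", 30)
  seed <- default("seed", 0)
  filter_kind <- default("filter", "ramp")
  min_fraction <- default("min_fraction", 0)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(cfg$tilt_series)) {
    if (is.null(cfg$angles)) stop("tilt-series input needs an `angles` file")
    if (is.null(cfg$nz)) stop("tilt-series input needs `nz`")
    imgs <- read_mrc(cfg$tilt_series, as = "stack")
    scheme <- read_tlt(cfg$angles)
    ts <- tilt_series(imgs, scheme, attr(imgs, "pixel_size_A"))
    sp <- split_even_odd(ts)
    shape <- c(cfg$nz, dim(imgs)[1], dim(imgs)[2])
    vol0 <- fbp(sp$half0, shape, filter_kind)
    vol1 <- fbp(sp$half1, shape, filter_kind)
    write_mrc(vol0, file.path(cfg$out_dir, "fbp_even.mrc"))
    write_mrc(vol1, file.path(cfg$out_dir, "fbp_odd.mrc"))
  } else if (!is.null(cfg$even) && !is.null(cfg$odd)) {
    vol0 <- read_mrc(cfg$even)
    vol1 <- read_mrc(cfg$odd)
  } else {
    stop("config must name either (`tilt_series`, `angles`) or ",
         "(`even`, `odd`)")
  }
  if (!identical(dim(vol0$data), dim(vol1$data))) {
    stop("the two half-volumes have inconsistent shapes")
  }

  positions <- plan_grid(dim(vol0$data), cube, overlap)
  if (min_fraction > 0) {
    mask <- content_mask(vol0)
    positions <- filter_positions(positions, mask, cube, min_fraction)
  }
  pairs <- extract_pairs(vol0, vol1, positions, cube)

  fcfg <- fit_config(
    alpha_max_deg = alpha, cube_size = cube, epochs = epochs,
    batch_size = default("batch_size", 4),
    learning_rate = default("learning_rate", 4e-4), seed = seed,
    unet = unet_config(base_channels = default("base_channels", 16),
                       depth = default("depth", 2),
                       dropout_p = default("dropout_p", 0))
  )
  eff <- c(cfg, list(alpha_max_deg = alpha, cube_size = cube,
                     overlap = overlap, epochs = epochs, seed = seed,
                     n_pairs = length(pairs),
                     package_version = as.character(
                       utils::packageVersion("wedgefill"))))
  yaml::write_yaml(eff, file.path(cfg$out_dir, "config.yaml"))

  res <- fit(pairs, fcfg)
  write.csv(res$history, file.path(cfg$out_dir, "loss.csv"),
            row.names = FALSE)
  save_model(res$model, file.path(cfg$out_dir, "model.ckpt"),
             fit_config = fcfg)

  refined <- refine_tomogram(vol0, vol1, res$model, cube, overlap)
  write_mrc(refined, file.path(cfg$out_dir, "refined.mrc"))

  metrics <- NULL
  if (!is.null(cfg$truth)) {
    truth <- read_mrc(cfg$truth)
    metrics <- data.frame(
      cc = cc(refined, truth),
      cc_outside_wedge = cc_outside_wedge(refined, truth, alpha),
      cc_inside_wedge = cc_inside_wedge(refined, truth, alpha)
    )
    write.csv(metrics, file.path(cfg$out_dir, "metrics.csv"),
              row.names = FALSE)
  }
  invisible(list(refined = refined, history = res$history,
                 metrics = metrics))
}
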