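#' Refine a tomogram with a fitted model
#'
#' Applies the fitted network to the original (non-wedge-updated)
#' sub-tomograms of both half-reconstructions over a full covering grid (no
#' content filtering), reassembles each half with uniform overlap
#' averaging, and returns the average of the two refined volumes.  Each
#' cube is standardized before the model and de-standardized afterwards, so
#' the output stays on the intensity scale of the inputs.
#'
#' @param vol0,vol1 The two half-reconstructions ([volume()] or array),
#'   identical shapes.
#' @param model A fitted `wf_unet` (or a plain function, e.g. `identity`).
#' @param cube_size Cube side accepted by the model.
#' @param overlap Grid overlap in voxels (default half the cube).
#' @return A [volume()] with the refined tomogram.
#' @export
refine_tomogram <- function(vol0, vol1, model, cube_size,
                            overlap = cube_size %/% 2) {
  a0 <- vol_data(vol0)
  a1 <- vol_data(vol1)
  if (!identical(dim(a0), dim(a1))) stop("half-volume shapes must match")
  positions <- plan_grid(dim(a0), cube_size, overlap)
  refine_half <- function(a) {
    cubes <- lapply(positions, function(p) {
      cube <- extract_cube(a, p, cube_size)
      m <- mean(cube)
      s <- sd(as.numeric(cube))
      if (!is.finite(s) || s == 0) return(cube)  # constant cube: pass through
      pred <- unet_predict(model, (cube - m) / s)
      pred * s + m
    })
    reassemble(cubes, positions, dim(a))
  }
  out <- (refine_half(a0) + refine_half(a1)) / 2
  vs <- if (inherits(vol0, "wf_volume")) vol0$voxel_size_A else 1
  volume(out, vs)
}
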