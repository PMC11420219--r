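#' Normalized correlation coefficient
#'
#' `CC(a, b) = <a - mean(a), b - mean(b)> / (||a - mean(a)|| ||b -
#' mean(b)||)`, the standard global similarity measure between a
#' reconstruction and its ground truth; invariant to affine intensity
#' changes with positive scale.
#'
#' @param a,b [volume()]s or arrays of identical shape, both non-constant.
#' @return Scalar in `[-1, 1]`.
#' @export
cc <- function(a, b) {
  x <- as.numeric(vol_data(a))
  y <- as.numeric(vol_data(b))
  if (!identical(dim(vol_data(a)), dim(vol_data(b)))) {
    stop("volume shapes must match")
  }
  x <- x - mean(x)
  y <- y - mean(y)
  nx <- sqrt(sum(x^2))
  ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) stop("correlation undefined for constant volumes")
  sum(x * y) / (nx * ny)
}

#' Correlation coefficient outside the missing wedge
#'
#' Applies the same missing-wedge filter to both volumes before computing
#' [cc()], so that differences living purely inside the wedge are
#' invisible; isolates denoising quality from wedge-filling quality.
#'
#' @inheritParams cc
#' @param alpha_max_deg Wedge angle in degrees.
#' @return Scalar correlation.
#' @export
cc_outside_wedge <- function(a, b, alpha_max_deg = 60) {
  m <- wedge_mask(dim(vol_data(a)), alpha_max_deg)
  cc(apply_mask(vol_data(a), m), apply_mask(vol_data(b), m))
}

#' Correlation coefficient inside the missing wedge
#'
#' Restricts both volumes to the wedge region (complement of the wedge
#' mask) before correlating; measures how well the unmeasured wedge content
#' was reconstructed.
#'
#' @inheritParams cc_outside_wedge
#' @return Scalar correlation.
#' @export
cc_inside_wedge <- function(a, b, alpha_max_deg = 60) {
  m <- complement_mask(wedge_mask(dim(vol_data(a)), alpha_max_deg))
  cc(apply_mask(vol_data(a), m), apply_mask(vol_data(b), m))
}

# shell index (0-based) for every voxel of the centered frequency grid
shell_index <- function(shape) {
  kz <- centered_freqs(shape[1])
  ky <- centered_freqs(shape[2])
  kx <- centered_freqs(shape[3])
  KZ2 <- array(kz^2, dim = shape)
  KY2 <- array(rep(ky^2, each = shape[1]), dim = shape)
  KX2 <- array(rep(kx^2, each = shape[1] * shape[2]), dim = shape)
  round(sqrt(KZ2 + KY2 + KX2))
}

fsc_core <- function(a, b, voxel_size_A, restrict = NULL) {
  da <- vol_data(a)
  db <- vol_data(b)
  if (!identical(dim(da), dim(db))) stop("volume shapes must match")
  n <- dim(da)[1]
  if (length(unique(dim(da))) != 1L) stop("FSC requires cubic volumes")
  Fa <- fftshift3(fft_u(da))
  Fb <- fftshift3(fft_u(db))
  sh <- shell_index(dim(da))
  ns <- n %/% 2
  keep <- sh <= ns
  if (!is.null(restrict)) keep <- keep & (restrict != 0)
  s <- sh[keep]
  num <- Re(Conj(Fa[keep]) * Fb[keep])
  pa <- Mod(Fa[keep])^2
  pb <- Mod(Fb[keep])^2
  agg <- function(x) {
    out <- rep(0, ns + 1)
    t <- tapply(x, s, sum)
    out[as.integer(names(t)) + 1] <- t
    out
  }
  sn <- agg(num)
  sa <- agg(pa)
  sb <- agg(pb)
  counts <- agg(rep(1, length(s)))
  # shells whose power is numerically zero (e.g. a masked-out wedge) carry
  # no information and are recorded as missing; "zero" is judged against
  # the volume's total spectral power
  tol_a <- 1e-20 * sum(Mod(Fa)^2)
  tol_b <- 1e-20 * sum(Mod(Fb)^2)
  vals <- ifelse(counts > 0 & sa > tol_a & sb > tol_b,
                 sn / sqrt(pmax(sa, .Machine$double.eps) *
                             pmax(sb, .Machine$double.eps)),
                 NA_real_)
  structure(
    list(shell_freqs = (0:ns) / n, values = vals,
         voxel_size_A = voxel_size_A, n = n),
    class = "wf_fsc"
  )
}

#' Fourier shell correlation
#'
#' Per radial shell `s` (width one frequency voxel, shells indexed by the
#' rounded radial frequency): `Re <Fa, Fb>_s / (||Fa||_s ||Fb||_s)`.
#' Shells that are empty (or have zero power) are recorded as `NA`.
#'
#' @param a,b Cubic [volume()]s or arrays of identical shape.
#' @param voxel_size_A Voxel size in Angstroms (taken from `a` if it is a
#'   [volume()]).
#' @return An object of class `wf_fsc` with `shell_freqs` (cycles/voxel, up
#'   to Nyquist 0.5) and `values`.
#' @export
fsc <- function(a, b, voxel_size_A = NULL) {
  if (is.null(voxel_size_A)) {
    voxel_size_A <- if (inherits(a, "wf_volume")) a$voxel_size_A else 1
  }
  fsc_core(a, b, voxel_size_A)
}

#' Fourier shell correlation inside the missing wedge
#'
#' Shell sums restricted to Fourier voxels with wedge mask 0 (the
#' unmeasured region); shells with no wedge voxels are `NA`.
#'
#' @inheritParams fsc
#' @param alpha_max_deg Wedge angle in degrees.
#' @return A `wf_fsc`.
#' @export
fsc_inside_wedge <- function(a, b, alpha_max_deg = 60, voxel_size_A = NULL) {
  if (is.null(voxel_size_A)) {
    voxel_size_A <- if (inherits(a, "wf_volume")) a$voxel_size_A else 1
  }
  m <- wedge_mask(dim(vol_data(a)), alpha_max_deg)
  fsc_core(a, b, voxel_size_A, restrict = 1 - m$data)
}

#' @export
print.wf_fsc <- function(x, ...) {
  cat(sprintf("<wf_fsc %d shells, voxel %.3g A, FSC(0.143) = %.3g A>\n",
              length(x$values), x$voxel_size_A, fsc_resolution(x)))
  invisible(x)
}

#' 0.143-cutoff resolution from an FSC curve
#'
#' First shell at which the FSC falls below the threshold; the resolution
#' is the inverse of that shell's spatial frequency in Angstroms
#' (`n * voxel / shell`).  If the curve never crosses, the Nyquist
#' resolution `2 * voxel` is returned.
#'
#' @param curve A `wf_fsc` from [fsc()] or [fsc_inside_wedge()].
#' @param threshold FSC threshold (default 0.143).
#' @return Resolution in Angstroms.
#' @export
fsc_resolution <- function(curve, threshold = 0.143) {
  stopifnot(inherits(curve, "wf_fsc"))
  v <- curve$values
  cross <- which(!is.na(v) & v < threshold & seq_along(v) > 1L)
  if (length(cross) == 0L) return(2 * curve$voxel_size_A)
  s <- cross[1] - 1  # 0-based shell index
  curve$n * curve$voxel_size_A / s
}
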