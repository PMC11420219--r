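#' Split a tilt series into even and odd acquisitions
#'
#' Partitions the projections by their order of acquisition (the stack
#' order): half 0 gets acquisition indices 0, 2, 4, ..., half 1 gets
#' 1, 3, 5, ...  Each half keeps its own tilt angles.  The two halves have
#' independent noise, which is the premise of the Noise2Noise-style loss.
#'
#' @param ts A [tilt_series()] with at least 2 projections.
#' @return A list of class `wf_split_pair` with fields `half0`, `half1`
#'   (tilt series) and `mode = "even_odd"`.
#' @export
split_even_odd <- function(ts) {
  stopifnot(inherits(ts, "wf_tilt_series"))
  p <- n_tilts(ts)
  if (p < 2L) stop("need at least 2 projections to split")
  i0 <- seq(1L, p, by = 2L)
  i1 <- seq(2L, p, by = 2L)
  mk <- function(idx) {
    tilt_series(ts$images[, , idx, drop = FALSE],
                tilt_scheme(ts$scheme$angles_deg[idx]), ts$pixel_size_A)
  }
  structure(list(half0 = mk(i0), half1 = mk(i1), mode = "even_odd"),
            class = "wf_split_pair")
}

#' Split per-tilt frame stacks into even and odd frame averages
#'
#' For dose-fractionated data: half 0 image k is the average of the
#' even-indexed frames recorded at tilt k (0-based acquisition order),
#' half 1 the average of the odd-indexed frames.  Both halves carry the
#' full tilt scheme.
#'
#' @param frames List with one `(ny, nx, F_k)` array per tilt, `F_k >= 2`.
#' @param scheme A [tilt_scheme()] with `length(frames)` angles.
#' @param pixel_size_A Pixel size in Angstroms.
#' @return A `wf_split_pair` with `mode = "frame_based"`.
#' @export
split_frames <- function(frames, scheme, pixel_size_A = 1) {
  stopifnot(is.list(frames), inherits(scheme, "wf_tilt_scheme"))
  if (length(frames) != length(scheme$angles_deg)) {
    stop("`frames` must have one stack per tilt angle")
  }
  nf <- vapply(frames, function(f) dim(f)[3], integer(1))
  if (any(nf < 2L)) stop("every tilt needs at least 2 frames")
  avg <- function(f, idx) {
    apply(f[, , idx, drop = FALSE], c(1, 2), mean)
  }
  d <- dim(frames[[1]])
  h0 <- array(0, dim = c(d[1], d[2], length(frames)))
  h1 <- h0
  for (k in seq_along(frames)) {
    fk <- dim(frames[[k]])[3]
    h0[, , k] <- avg(frames[[k]], seq(1L, fk, by = 2L)) # frames 0,2,4,...
    h1[, , k] <- avg(frames[[k]], seq(2L, fk, by = 2L)) # frames 1,3,5,...
  }
  structure(
    list(half0 = tilt_series(h0, scheme, pixel_size_A),
         half1 = tilt_series(h1, scheme, pixel_size_A),
         mode = "frame_based"),
    class = "wf_split_pair"
  )
}

# 1D frequency response along x, length n (natural fft order)
fbp_filter_response <- function(n, filter_kind) {
  f <- abs(centered_freqs(n)[c((n %/% 2 + 1):n, seq_len(n %/% 2))]) / n
  switch(filter_kind,
    ramp = f,
    hamming = f * (0.54 + 0.46 * cos(pi * f / 0.5)),
    stop("unknown `filter_kind`: ", filter_kind)
  )
}

#' Filtered back-projection of a single-axis tilt series
#'
#' Stacked 2D reconstructions over the tilt (y) axis: each projection row is
#' filtered along x with a 1D frequency filter (ramp `|f|` or a
#' Hamming-windowed ramp `|f| (0.54 + 0.46 cos(pi f / f_Nyq))`), then
#' back-projected over the scheme's angles with uniform angular weighting
#' and normalized by `pi / K` (`K` projections), the classical factor that
#' recovers the input scale for a dense 180-degree scheme.
#'
#' @param ts A [tilt_series()].
#' @param out_shape Integer `(nz, ny, nx)`; `ny`, `nx` must match the
#'   projection images.
#' @param filter_kind `"ramp"` or `"hamming"`.
#' @return A [volume()].
#' @export
fbp <- function(ts, out_shape, filter_kind = c("ramp", "hamming")) {
  stopifnot(inherits(ts, "wf_tilt_series"))
  filter_kind <- match.arg(filter_kind)
  out_shape <- as.integer(out_shape)
  d <- dim(ts$images)
  if (length(out_shape) != 3L || out_shape[2] != d[1] ||
      out_shape[3] != d[2]) {
    stop("`out_shape` (nz, ny, nx) must match projection images (ny, nx)")
  }
  resp <- fbp_filter_response(d[2], filter_kind)
  # filter along x: images are (y, x, k); fft row-wise over x
  filt <- array(0, dim = d)
  for (k in seq_len(d[3])) {
    img <- ts$images[, , k]
    ft <- t(stats::mvfft(t(img)))            # fft along x for each y-row
    ft <- sweep(ft, 2, resp, `*`)
    filt[, , k] <- Re(t(stats::mvfft(t(ft), inverse = TRUE))) / d[2]
  }
  vol_vec <- cpp_backproject(as.numeric(filt), d[1], d[2],
                             ts$scheme$angles_deg * pi / 180, out_shape[1])
  v <- array(vol_vec, dim = out_shape) * pi / d[3]
  volume(v, ts$pixel_size_A)
}
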