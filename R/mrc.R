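#' @name mrc
#' @title MRC2014 and .tlt input/output
#'
#' @description
#' Minimal MRC2014 reader/writer for real-valued volumes and image stacks
#' (mode 2, float32, little-endian) and IMOD-dialect `.tlt` angle files
#' (one angle in degrees per line).  On disk the x index is fastest and
#' sections are slowest, so volumes are transposed between the package's
#' `(z, y, x)` array order and the file order.
NULL

#' Write a volume or tilt series to an MRC file
#'
#' @param x A [volume()] or [tilt_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(x, path) {
  if (inherits(x, "wf_volume")) {
    d <- dim(x$data)                # (nz, ny, nx)
    nxyz <- c(d[3], d[2], d[1])     # file order: nx, ny, nz
    dat <- aperm(x$data, c(3, 2, 1))
    psize <- x$voxel_size_A
  } else if (inherits(x, "wf_tilt_series")) {
    d <- dim(x$images)              # (ny, nx, P)
    nxyz <- c(d[2], d[1], d[3])
    dat <- aperm(x$images, c(2, 1, 3))
    psize <- x$pixel_size_A
  } else {
    stop("`x` must be a wf_volume or wf_tilt_series")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  wf <- function(v) writeBin(as.numeric(v), con, size = 4, endian = "little")
  wi(nxyz)                         # nx ny nz
  wi(2)                            # mode 2: float32
  wi(c(0, 0, 0))                   # nxstart nystart nzstart
  wi(nxyz)                         # mx my mz
  wf(nxyz * psize)                 # cella
  wf(c(90, 90, 90))                # cellb
  wi(c(1, 2, 3))                   # mapc mapr maps
  wf(c(min(dat), max(dat), mean(dat)))
  wi(c(0, 0))                      # ispg, nsymbt
  wi(rep(0, 25))                   # extra
  wf(c(0, 0, 0))                   # origin
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(sd(as.numeric(dat)))          # rms
  wi(0)                            # nlabl
  writeBin(raw(800), con)          # labels
  wf(dat)
  invisible(path)
}

#' Read an MRC file
#'
#' @param path Input file path.
#' @param as `"volume"` to return a [volume()]; `"stack"` to return the raw
#'   `(ny, nx, P)` image array with pixel size as attribute.
#' @return A [volume()] or an image array.
#' @export
read_mrc <- function(path, as = c("volume", "stack")) {
  as <- match.arg(as)
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  nxyz <- ri(3)
  mode <- ri(1)
  if (mode != 2) stop("only MRC mode 2 (float32) is supported")
  ri(3)                            # starts
  ri(3)                            # mx my mz
  cella <- rf(3)
  seek(con, 1024)
  n <- prod(nxyz)
  dat <- array(rf(n), dim = nxyz)  # (x, y, sections)
  psize <- if (nxyz[1] > 0 && cella[1] > 0) cella[1] / nxyz[1] else 1
  if (as == "volume") {
    volume(aperm(dat, c(3, 2, 1)), psize)
  } else {
    out <- aperm(dat, c(2, 1, 3))
    attr(out, "pixel_size_A") <- psize
    out
  }
}

#' Write tilt angles to an IMOD-dialect .tlt file
#'
#' @param scheme A [tilt_scheme()] or numeric vector of angles in degrees.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tlt <- function(scheme, path) {
  a <- if (inherits(scheme, "wf_tilt_scheme")) scheme$angles_deg else scheme
  writeLines(formatC(a, format = "f", digits = 2), path)
  invisible(path)
}

#' Read a .tlt angle file
#'
#' @param path Input file path.
#' @return A [tilt_scheme()].
#' @export
read_tlt <- function(path) {
  tilt_scheme(as.numeric(readLines(path)))
}

#' Write grid positions to a plain-text table
#'
#' @param positions List of grid positions (as from [plan_grid()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_positions <- function(positions, path) {
  m <- do.call(rbind, positions)
  write.table(m, path, row.names = FALSE, col.names = c("z0", "y0", "x0"))
  invisible(path)
}

#' Read grid positions from a plain-text table
#'
#' @param path Input file path.
#' @return A list of integer `(z0, y0, x0)` corner offsets.
#' @export
read_positions <- function(path) {
  m <- as.matrix(read.table(path, header = TRUE))
  lapply(seq_len(nrow(m)), function(i) as.integer(m[i, ]))
}

#' Export a wedge mask as an MRC volume
#'
#' @param mask A `wf_wedge_mask`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mask_mrc <- function(mask, path) {
  write_mrc(volume(mask$data, 1), path)
}
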