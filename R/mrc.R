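# MRC2014 I/O on binary connections.  Only the fields the format requires
# are interpreted; data are written in mode 2 (float32) and read from
# modes 0/1/2 with promotion to double.  The on-disk fastest axis (x, MRC
# "columns") matches the in-memory fastest axis, so the array maps to the
# file with no permutation.

.mrc_header_template <- function() {
  list(
    nx = 0L, ny = 0L, nz = 0L, mode = 2L,
    nxstart = 0L, nystart = 0L, nzstart = 0L,
    mx = 0L, my = 0L, mz = 0L,
    cella = c(0, 0, 0), cellb = c(90, 90, 90),
    mapc = 1L, mapr = 2L, maps = 3L,
    dmin = 0, dmax = 0, dmean = 0,
    ispg = 1L, nsymbt = 0L
  )
}

#' Write a volume as an MRC2014 file
#'
#' Data are stored in mode 2 (32-bit float), x fastest, with a compliant
#' 1024-byte header carrying the grid size, cell dimensions derived from
#' `voxel_size`, and density statistics.
#'
#' @param v A [volume()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_volume()]
#' @export
write_volume <- function(v, path) {
  stopifnot_volume(v)
  d <- dim(v$data)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  # data as float32 (written at the end); header stats computed on the
  # float32-truncated values so they match the payload exactly
  dat <- v$data
  wi(d)                       # nx ny nz
  wi(2L)                      # mode 2 = float32
  wi(c(0L, 0L, 0L))           # nxstart nystart nzstart
  wi(d)                       # mx my mz
  wf(d * v$voxel_size)        # cella
  wf(c(90, 90, 90))           # cellb
  wi(c(1L, 2L, 3L))           # mapc mapr maps
  wf(c(min(dat), max(dat), mean(dat)))  # dmin dmax dmean
  wi(1L)                      # ispg: 3D volume
  wi(0L)                      # nsymbt
  wi(rep(0L, 2L))             # extra (words 25-26)
  wi(0L)                      # exttyp (word 27; none)
  wi(20140L)                  # nversion (word 28)
  writeBin(raw(84L), con)     # remainder of extra space (words 29-49)
  wf(c(0, 0, 0))              # origin
  writeChar("MAP ", con, nchars = 4L, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst: little-endian
  wf(stats::sd(dat))          # rms
  wi(0L)                      # nlabl
  writeBin(raw(800L), con)    # labels
  wf(dat)
  invisible(path)
}

#' Read an MRC2014 volume
#'
#' Accepts data modes 0 (int8), 1 (int16) and 2 (float32); values are
#' promoted to double.  The voxel size is recovered from the cell
#' dimensions.  A header whose grid size disagrees with the file length
#' raises an error rather than truncating silently.
#'
#' @param path Path to an MRC file.
#' @return A [volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n = n, size = 4L, endian = "little")
  rf <- function(n) readBin(con, "numeric", n = n, size = 4L, endian = "little")
  dims <- ri(3L)
  mode <- ri(1L)
  ri(3L)                      # nxstart..
  mgrid <- ri(3L)
  cella <- rf(3L)
  rf(3L)                      # cellb
  ri(3L)                      # mapc mapr maps
  rf(3L)                      # dmin dmax dmean
  ri(2L)                      # ispg nsymbt
  readBin(con, "raw", n = 100L)  # extra
  rf(3L)                      # origin
  magic <- readChar(con, nchars = 4L, useBytes = TRUE)
  if (!identical(magic, "MAP ")) {
    stop(sprintf("not an MRC2014 file (magic '%s', expected 'MAP ')", magic))
  }
  readBin(con, "raw", n = 4L)    # machst
  rf(1L)                      # rms
  ri(1L)                      # nlabl
  readBin(con, "raw", n = 800L)  # labels
  if (any(dims < 1L)) stop("MRC header declares non-positive dimensions")
  n <- prod(dims)
  dat <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n = n, size = 1L, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", n = n, size = 2L,
                             endian = "little")),
    "2" = readBin(con, "numeric", n = n, size = 4L, endian = "little"),
    stop(sprintf("unsupported MRC mode %d (modes 0/1/2 are supported)", mode))
  )
  if (length(dat) != n) {
    stop(sprintf(
      "MRC data truncated: header declares %d voxels, file holds %d",
      n, length(dat)
    ))
  }
  vs <- if (mgrid[1] > 0 && cella[1] > 0) cella[1] / mgrid[1] else 1.0
  volume(array(dat, dim = dims), voxel_size = vs)
}
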