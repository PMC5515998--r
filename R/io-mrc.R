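# Minimal MRC/MRCS reader and writer (CCP-EM standard 1024-byte header,
# mode 2 float32, little-endian). Volumes come back as volume3d, single
# images as image2d, stacks (nz > 1 with MRCS extension or non-cubic
# shape) as b x b x n arrays. In-memory axis order is a[ix, iy, iz] with
# x fastest; voxel size is taken from cella / mx.

#' Write a volume, image or stack to an MRC file
#'
#' @param x A [volume3d()], [image2d()], matrix, or 3D array (stack of
#'   images when `stack = TRUE` or the path ends in `.mrcs`).
#' @param path Output path.
#' @param pixel_size Pixel size in Angstrom (taken from `x` when it is a
#'   package object).
#' @param stack Force stack interpretation of a 3D array.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(x, path, pixel_size = NULL, stack = NULL) {
  if (inherits(x, "volume3d")) {
    data <- x$density
    pixel_size <- x$voxel_size
    is_stack <- FALSE
  } else if (inherits(x, "image2d")) {
    data <- array(x$pixels, c(dim(x$pixels), 1))
    pixel_size <- x$pixel_size
    is_stack <- FALSE
  } else if (is.matrix(x)) {
    data <- array(x, c(dim(x), 1))
    is_stack <- FALSE
  } else {
    data <- x
    is_stack <- if (is.null(stack)) grepl("\\.mrcs$", path) else stack
  }
  if (is.null(pixel_size)) pixel_size <- 1
  d <- dim(data)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  wf <- function(v) writeBin(as.numeric(v), con, size = 4, endian = "little")
  wi(d)                               # nx ny nz
  wi(2)                               # mode 2 = float32
  wi(c(0, 0, 0))                      # nxstart
  wi(d)                               # mx my mz
  wf(d * pixel_size)                  # cella
  wf(c(90, 90, 90))                   # cellb
  wi(c(1, 2, 3))                      # mapc mapr maps
  wf(c(min(data), max(data), mean(data)))
  wi(if (is_stack) 0 else 1)          # ispg: 0 marks an image stack
  wi(0)                               # nsymbt
  wi(rep(0, 25))                      # extra
  wf(c(0, 0, 0))                      # origin
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(sd(as.numeric(data)))
  wi(0)                               # nlabl
  writeBin(raw(800), con)             # labels
  wf(as.numeric(data))
  invisible(path)
}

#' Read an MRC/MRCS file
#'
#' Supports modes 0 (int8), 1 (int16), 2 (float32) and 6 (uint16).
#' Cubic volumes (nz == nx, and not flagged/named as a stack) return a
#' [volume3d()]; nz == 1 returns an [image2d()]; anything else a
#' `nx x ny x nz` array with attribute `pixel_size`.
#'
#' @param path Input path.
#' @return See details.
#' @export
read_mrc <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  d <- ri(3)
  mode <- ri(1)
  if (any(d <= 0) || any(d > 1e5))
    stop_invalid("invalid MRC header: bad dimensions (nx ny nz = %s)",
                 paste(d, collapse = " "))
  if (!mode %in% c(0, 1, 2, 6))
    stop_invalid("invalid MRC header: unsupported mode %d", mode)
  ri(3)                               # nxstart
  mx <- ri(3)
  cella <- rf(3)
  if (any(mx <= 0) || any(abs(mx - d) > 0))
    stop_invalid("invalid MRC header: mx/my/mz (%s) do not match nx/ny/nz (%s)",
                 paste(mx, collapse = " "), paste(d, collapse = " "))
  pixel_size <- cella[1] / mx[1]
  if (!is.finite(pixel_size) || pixel_size <= 0) pixel_size <- 1
  rf(3)                               # cellb
  ri(3)                               # mapc mapr maps
  rf(3)                               # dmin dmax dmean
  ispg <- ri(1)
  nsymbt <- ri(1)
  seek(con, 1024 + nsymbt)
  nvox <- prod(d)
  data <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", nvox, size = 1, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", nvox, size = 2,
                             endian = "little")),
    "2" = readBin(con, "numeric", nvox, size = 4, endian = "little"),
    "6" = as.numeric(readBin(con, "integer", nvox, size = 2, signed = FALSE,
                             endian = "little")))
  if (length(data) < nvox)
    stop_invalid("truncated MRC data: expected %d voxels, got %d",
                 nvox, length(data))
  a <- array(data, d)
  is_stack <- grepl("\\.mrcs$", path) || (ispg == 0 && d[3] > 1)
  if (d[3] == 1) {
    image2d(a[, , 1], pixel_size)
  } else if (!is_stack && d[1] == d[2] && d[2] == d[3]) {
    volume3d(a, pixel_size)
  } else {
    attr(a, "pixel_size") <- pixel_size
    a
  }
}
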