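#' Density volumes
#'
#' A `volume_grid` carries a 3-D numeric array of densities plus the voxel
#' size in angstrom. The origin convention marker records how the volume's
#' coordinate origin is interpreted (`"corner"`: voxel \code{[1,1,1]} is the
#' coordinate origin).
#'
#' @param data 3-D numeric array; all three dimensions must be >= 2.
#' @param voxel_size_A voxel size in angstrom (> 0).
#' @param origin origin convention marker.
#' @return an object of class `volume_grid`.
#' @export
volume_grid <- function(data, voxel_size_A, origin = "corner") {
  if (!is.array(data) || length(dim(data)) != 3) {
    abort_fib("volume data must be a 3-D array", "fib_format_error")
  }
  if (any(dim(data) < 2)) {
    abort_fib("not a volume: all three dimensions must be >= 2",
              "fib_format_error")
  }
  if (!is_scalar_number(voxel_size_A) || voxel_size_A <= 0) {
    abort_fib("voxel_size_A must be a positive number", "fib_format_error")
  }
  structure(list(data = data, voxel_size_A = voxel_size_A, origin = origin),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid %s, %.4g A/voxel>\n",
              paste(dim(x$data), collapse = "x"), x$voxel_size_A))
  invisible(x)
}

#' Read an MRC volume
#'
#' Minimal MRC2014 reader for mode 0 (int8), 1 (int16) and 2 (float32)
#' volumes. The voxel size is taken as `cella / mx` from the header.
#'
#' @param path path to an MRC file.
#' @param voxel_size_A override used when the header voxel size is zero.
#' @return a [volume_grid()].
#' @export
read_volume <- function(path, voxel_size_A = NULL) {
  if (!file.exists(path)) {
    abort_fib(sprintf("file not found: %s", path), "fib_io_error")
  }
  fsize <- file.info(path)$size
  if (fsize < 1024) abort_fib("truncated MRC file: header incomplete",
                              "fib_format_error")
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  nx <- hdr_int[1]; ny <- hdr_int[2]; nz <- hdr_int[3]; mode <- hdr_int[4]
  mx <- hdr_int[8]
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  if (nx <= 0 || ny <= 0 || nz <= 0) {
    abort_fib("invalid MRC header: non-positive dimensions",
              "fib_format_error")
  }
  if (nz < 2 || ny < 2 || nx < 2) {
    abort_fib("not a volume: MRC file has a dimension < 2",
              "fib_format_error")
  }
  bytes_per <- switch(as.character(mode), "0" = 1L, "1" = 2L, "2" = 4L, NULL)
  if (is.null(bytes_per)) {
    abort_fib(sprintf("unsupported MRC mode %d", mode), "fib_format_error")
  }
  # nsymbt at header word 24 (offset 92 bytes)
  seek(con, 92)
  nsymbt <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  nvox <- as.double(nx) * ny * nz
  expected <- 1024 + nsymbt + nvox * bytes_per
  if (fsize < expected) {
    abort_fib("truncated MRC file: header/data size mismatch",
              "fib_format_error")
  }
  seek(con, 1024 + nsymbt)
  raw_vals <- if (mode == 2) {
    readBin(con, "numeric", n = nvox, size = 4, endian = "little")
  } else {
    readBin(con, "integer", n = nvox, size = bytes_per, signed = TRUE,
            endian = "little")
  }
  vox <- if (mx > 0) cella[1] / mx else 0
  if (vox <= 0) {
    if (is.null(voxel_size_A)) {
      abort_fib("MRC header voxel size is zero; supply voxel_size_A",
                "fib_format_error")
    }
    vox <- voxel_size_A
  }
  volume_grid(array(as.numeric(raw_vals), dim = c(nx, ny, nz)),
              voxel_size_A = vox)
}

#' Write an MRC volume
#'
#' Writes mode-2 (float32) little-endian MRC2014.
#'
#' @param volume a [volume_grid()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "volume_grid"))
  d <- dim(volume$data)
  con <- tryCatch(file(path, "wb"),
                  error = function(e) abort_fib(
                    sprintf("cannot open '%s' for writing", path),
                    "fib_io_error"))
  on.exit(close(con))
  vals <- as.numeric(volume$data)
  writeBin(as.integer(c(d, 2L, 0L, 0L, 0L, d)), con, size = 4,
           endian = "little")                                   # words 1-10
  writeBin(as.numeric(c(d * volume$voxel_size_A, 90, 90, 90)), con,
           size = 4, endian = "little")                         # cella, cellb
  writeBin(1:3, con, size = 4, endian = "little")               # mapc/r/s
  writeBin(as.numeric(c(min(vals), max(vals), mean(vals))), con,
           size = 4, endian = "little")                         # dmin/max/mean
  writeBin(c(1L, 0L), con, size = 4, endian = "little")         # ispg, nsymbt
  writeBin(raw(100), con)                                       # extra
  writeBin(numeric(3), con, size = 4, endian = "little")        # origin
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)              # machst LE
  writeBin(as.numeric(sd(vals)), con, size = 4, endian = "little")
  writeBin(0L, con, size = 4, endian = "little")                # nlabl
  writeBin(raw(800), con)                                       # labels
  writeBin(vals, con, size = 4, endian = "little")
  invisible(path)
}
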