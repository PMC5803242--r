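# File formats: MRC2014 volumes/stacks (minimal reader/writer, mode 2
# float32, little-endian), single-image TIFF, plain-text tilt-angle (.tlt)
# files and YAML denoising configurations.

#' Write a volume or image stack as MRC2014 (mode 2, float32)
#'
#' Volumes are written with `ispg = 1`, 2-D images and stacks with
#' `ispg = 0`. Data are stored little-endian, x fastest, matching the
#' in-memory layout of R arrays.
#'
#' @param data numeric 2-D or 3-D array.
#' @param path output file path.
#' @param voxel_size physical voxel size in Angstrom (scalar or length 3),
#'   stored in the cell dimensions.
#' @param is_stack force stack semantics (`ispg = 0`) for a 3-D array whose
#'   third axis is a collection of images rather than a spatial axis.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(data, path, voxel_size = 1, is_stack = FALSE) {
  check_image(data, "data")
  d <- dim(data)
  if (length(d) == 2L) d <- c(d, 1L)
  voxel_size <- rep(as.numeric(voxel_size), length.out = 3L)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L,
                             endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L,
                             endian = "little")
  wi(d)                       # nx ny nz
  wi(2L)                      # mode 2: float32
  wi(c(0L, 0L, 0L))           # nxstart nystart nzstart
  wi(d)                       # mx my mz
  wf(d * voxel_size)          # cella
  wf(c(90, 90, 90))           # cellb
  wi(c(1L, 2L, 3L))           # mapc mapr maps
  wf(c(min(data), max(data), mean(data)))  # dmin dmax dmean
  wi(if (length(dim(data)) == 3L && !is_stack) 1L else 0L)  # ispg
  wi(0L)                      # nsymbt
  wi(rep(0L, 25L))            # extra
  wf(c(0, 0, 0))              # origin
  writeChar("MAP ", con, nchars = 4L, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst: little-endian
  wf(stats::sd(as.numeric(data)))                   # rms
  wi(0L)                      # nlabl
  writeBin(raw(800L), con)    # labels
  writeBin(as.numeric(data), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read an MRC2014 volume or stack
#'
#' Supports modes 0 (int8), 1 (int16), 2 (float32) and 6 (uint16),
#' little-endian. Non-finite voxel values are rejected.
#'
#' @param path input file path.
#' @return Numeric array (`nx x ny` if nz = 1, else `nx x ny x nz`) with a
#'   `"voxel_size"` attribute (Angstrom per voxel).
#' @export
read_mrc <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4L, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4L, endian = "little")
  d <- ri(3L)
  mode <- ri(1L)
  ri(3L)             # starts
  m <- ri(3L)
  cella <- rf(3L)
  seek(con, 1024L)
  n <- prod(d)
  data <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n, size = 1L, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", n, size = 2L, signed = TRUE,
                             endian = "little")),
    "2" = readBin(con, "numeric", n, size = 4L, endian = "little"),
    "6" = as.numeric(readBin(con, "integer", n, size = 2L, signed = FALSE,
                             endian = "little")),
    stopf("unsupported MRC mode %d", mode))
  if (length(data) != n) stopf("truncated MRC data in %s", path)
  if (anyNA(data) || any(!is.finite(data)))
    stopf("MRC file %s contains non-finite values", path)
  out <- if (d[3L] == 1L) array(data, d[1:2]) else array(data, d)
  attr(out, "voxel_size") <- ifelse(m > 0, cella / m, 1)
  out
}

#' Write a 2-D image as 32-bit float TIFF
#' @param image numeric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tiff_image <- function(image, path) {
  check_image(image, "image")
  if (length(dim(image)) != 2L) stopf("TIFF export is for 2-D images")
  tiff::writeTIFF(image, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' Read a 2-D TIFF image
#' @param path input path.
#' @return Numeric matrix; non-finite values are rejected.
#' @export
read_tiff_image <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  img <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img <- unclass(as.matrix(img))
  if (anyNA(img) || any(!is.finite(img)))
    stopf("TIFF file %s contains non-finite values", path)
  img
}

#' Write tilt angles as a plain-text .tlt file (one angle per line, degrees)
#' @param angles_deg numeric vector of angles.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tlt <- function(angles_deg, path) {
  writeLines(formatC(angles_deg, format = "f", digits = 2), path)
  invisible(path)
}

#' Read a plain-text .tlt tilt-angle file
#' @param path input path.
#' @return Numeric vector of angles in degrees.
#' @export
read_tlt <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  as.numeric(readLines(path))
}

#' Serialize a denoising configuration to YAML
#' @param cfg a [denoise_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_denoise_config <- function(cfg, path) {
  if (!inherits(cfg, "denoise_config")) stopf("'cfg' must be a denoise_config")
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Read a denoising configuration from YAML
#' @param path input path.
#' @return A validated [denoise_config()].
#' @export
read_denoise_config <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  raw <- yaml::read_yaml(path)
  do.call(denoise_config, raw)
}
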