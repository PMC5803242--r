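# Simulation inputs: a deterministic geometric phantom, Gaussian noise
# calibrated to a target SNR, and a parallel-beam tilt series. Volumes are
# stored as (x, y, z) arrays with y the vertical tilt axis and z the beam
# direction at zero tilt.

#' Phantom specification
#'
#' A deterministic multi-primitive density phantom. Each primitive adds its
#' intensity to every voxel it covers. Supported kinds:
#' `sphere` (size = radius), `ellipsoid` (size = 3 semi-axes),
#' `cylinder` (axis along y; size = radius, half-length),
#' `box` (size = 3 half-edges).
#'
#' @param shape three positive integers (default `c(64, 64, 64)`).
#' @param primitives list of primitives, each a list with fields `kind`,
#'   `center` (3 coordinates, voxel units), `size`, `intensity`. Defaults to
#'   [default_phantom_primitives()].
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64L, 64L, 64L),
                         primitives = default_phantom_primitives(shape)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 2L))
    stopf("'shape' must be three integers >= 2")
  for (p in primitives) {
    if (!p$kind %in% c("sphere", "ellipsoid", "cylinder", "box"))
      stopf("unknown primitive kind '%s'", p$kind)
    ext <- primitive_extent(p)
    if (any(p$center - ext < 1) || any(p$center + ext > shape))
      stopf("a %s primitive extends outside the volume", p$kind)
    if (!all(is.finite(p$intensity))) stopf("primitive intensity not finite")
  }
  structure(list(shape = shape, primitives = primitives),
            class = "phantom_spec")
}

#' Default phantom primitives
#'
#' Six primitives spanning coarse and fine scales so that both smoothing and
#' detail preservation are exercised: a large low-contrast ellipsoid body,
#' three spheres of decreasing radius and increasing contrast, one thin
#' vertical cylinder, and a small box. All primitives lie inside the
#' cylinder inscribed about the vertical axis, so parallel-beam projections
#' conserve their mass at every tilt angle. Coordinates scale with `shape`.
#'
#' @param shape the target volume shape (three integers).
#' @return A list of primitive definitions for [phantom_spec()].
#' @export
default_phantom_primitives <- function(shape = c(64L, 64L, 64L)) {
  s <- shape / 64  # scale factors relative to the reference 64^3 design
  pr <- function(kind, center, size, intensity)
    list(kind = kind, center = center, size = size, intensity = intensity)
  list(
    pr("ellipsoid", c(32.5, 32.5, 32.5) * s, c(20, 16, 14) * min(s), 1.0),
    pr("sphere",    c(24, 26, 28) * s, 6 * min(s),   1.5),
    pr("sphere",    c(40, 38, 30) * s, 4 * min(s),   2.0),
    pr("sphere",    c(34, 22, 40) * s, 2.5 * min(s), 2.5),
    pr("cylinder",  c(28, 32.5, 24) * s, c(1.5 * min(s), 12 * s[2]), 2.0),
    pr("box",       c(38, 44, 38) * s, c(4, 3, 2) * min(s), 1.2)
  )
}

#' @keywords internal
#' @noRd
primitive_extent <- function(p) {
  switch(p$kind,
         sphere = rep(p$size[1L], 3L),
         ellipsoid = p$size,
         cylinder = c(p$size[1L], p$size[2L], p$size[1L]),
         box = p$size)
}

#' Render a phantom volume from its specification
#'
#' Deterministic: the same spec always produces a bit-identical volume.
#' Voxel value is the sum of intensities of the primitives covering the
#' voxel center; background is 0.
#'
#' @param spec a [phantom_spec()].
#' @return Numeric 3-D array of `spec$shape`.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  d <- spec$shape
  x <- seq_len(d[1L]); y <- seq_len(d[2L]); z <- seq_len(d[3L])
  vol <- array(0, dim = d)
  gx <- array(rep(x, times = d[2L] * d[3L]), d)
  gy <- array(rep(rep(y, each = d[1L]), times = d[3L]), d)
  gz <- array(rep(z, each = d[1L] * d[2L]), d)
  for (p in spec$primitives) {
    inside <- switch(p$kind,
      sphere = ((gx - p$center[1L])^2 + (gy - p$center[2L])^2 +
                  (gz - p$center[3L])^2) <= p$size[1L]^2,
      ellipsoid = ((gx - p$center[1L])^2 / p$size[1L]^2 +
                     (gy - p$center[2L])^2 / p$size[2L]^2 +
                     (gz - p$center[3L])^2 / p$size[3L]^2) <= 1,
      cylinder = (((gx - p$center[1L])^2 + (gz - p$center[3L])^2)
                  <= p$size[1L]^2) & (abs(gy - p$center[2L]) <= p$size[2L]),
      box = (abs(gx - p$center[1L]) <= p$size[1L]) &
        (abs(gy - p$center[2L]) <= p$size[2L]) &
        (abs(gz - p$center[3L]) <= p$size[3L]))
    vol <- vol + p$intensity * inside
  }
  vol
}

#' Binary evaluation mask: phantom support dilated by a margin
#'
#' The support (non-zero voxels) of a reference volume dilated by `dilate`
#' voxels with a cubic structuring element. Used as the "suitable mask" for
#' the simulation metrics, restricting evaluation to the object region.
#'
#' @param reference numeric array (typically a phantom).
#' @param dilate dilation radius in voxels (default 2).
#' @return Logical array of the same shape.
#' @export
phantom_mask <- function(reference, dilate = 2L) {
  check_image(reference, "reference")
  supp <- (reference != 0) * 1
  if (dilate > 0L) supp <- box_filter(supp, 2L * as.integer(dilate) + 1L)
  array(supp > 1e-12, dim = dim(reference))
}

#' Add Gaussian noise calibrated to a target SNR
#'
#' Adds i.i.d. Gaussian noise with
#' \eqn{\sigma = \sqrt{\mathrm{Var}_{mask}(I) / \mathrm{SNR}}} so the
#' population variance-ratio SNR equals `target_snr`. The default target of
#' 0.1 matches the noise level of a real cryo-tomogram. Reproducible under
#' `seed`; the caller's RNG state is left untouched.
#'
#' @param image numeric array, non-constant within the mask.
#' @param target_snr positive target variance ratio (default 0.1).
#' @param seed integer seed.
#' @param mask optional binary array: region over which the signal variance
#'   is measured (default: whole image).
#' @return Noisy array of the same shape.
#' @export
add_noise_to_snr <- function(image, target_snr = 0.1, seed = 1L,
                             mask = NULL) {
  check_image(image)
  if (!is.numeric(target_snr) || target_snr <= 0)
    stopf("'target_snr' must be > 0")
  vals <- if (is.null(mask)) as.numeric(image)
          else as.numeric(image)[as.logical(mask)]
  v <- stats::var(vals)
  if (!is.finite(v) || v == 0)
    stopf("image is constant within the mask; SNR calibration impossible")
  sigma <- sqrt(v / target_snr)
  noise <- with_seed(seed, stats::rnorm(length(image), sd = sigma))
  image + array(noise, dim = dim(image))
}

#' Tilt-series container
#'
#' @param projections 3-D array `nx x ny x n_angles` of projection images.
#' @param angles_deg strictly increasing tilt angles in degrees.
#' @param axis label of the tilt axis (always the vertical `"y"` axis).
#' @return A list of class `tilt_series`.
#' @export
tilt_series <- function(projections, angles_deg, axis = "y") {
  if (length(dim(projections)) != 3L)
    stopf("'projections' must be a 3-D stack")
  if (dim(projections)[3L] != length(angles_deg))
    stopf("number of projections (%d) and angles (%d) differ",
          dim(projections)[3L], length(angles_deg))
  if (is.unsorted(angles_deg, strictly = TRUE))
    stopf("'angles_deg' must be strictly increasing")
  structure(list(projections = projections,
                 angles_deg = as.numeric(angles_deg), axis = axis),
            class = "tilt_series")
}

#' @export
print.tilt_series <- function(x, ...) {
  d <- dim(x$projections)
  cat(sprintf("tilt_series: %d projections of %dx%d, angles %g..%g deg\n",
              d[3L], d[1L], d[2L], min(x$angles_deg), max(x$angles_deg)))
  invisible(x)
}

#' Parallel-beam projection of a volume over a tilt range
#'
#' For each angle the volume is rotated about the vertical (y) axis with
#' bilinear interpolation and summed along the beam (z) axis, producing
#' parallel-beam line integrals on an `nx x ny` detector. Samples rotated
#' outside the volume contribute zero, so objects should lie inside the
#' inscribed cylinder for exact mass conservation.
#'
#' @param volume numeric 3-D array (x, y, z).
#' @param angles_deg strictly increasing tilt angles, each in (-90, 90).
#' @return A [tilt_series()].
#' @export
project_tilt_series <- function(volume, angles_deg = seq(-70, 70, by = 1)) {
  check_image(volume)
  if (length(dim(volume)) != 3L) stopf("'volume' must be 3-D")
  if (any(abs(angles_deg) >= 90))
    stopf("tilt angles must lie strictly inside (-90, 90) degrees")
  ops <- projection_operators(dim(volume), angles_deg)
  d <- dim(volume)
  vm <- vol_to_mat(volume)
  proj <- array(0, dim = c(d[1L], d[2L], length(angles_deg)))
  for (a in seq_along(angles_deg))
    proj[, , a] <- as.matrix(ops[[a]] %*% vm)
  tilt_series(proj, angles_deg)
}

#' Project, then add per-projection calibrated Gaussian noise
#'
#' Composes [project_tilt_series()] and [add_noise_to_snr()]; the noise SD
#' is calibrated per projection image from that image's own variance.
#' Deterministic under `seed`.
#'
#' @inheritParams project_tilt_series
#' @param target_snr positive target variance ratio (default 0.1).
#' @param seed integer seed.
#' @return A noisy [tilt_series()].
#' @export
noisy_tilt_series <- function(volume, angles_deg = seq(-70, 70, by = 1),
                              target_snr = 0.1, seed = 1L) {
  ts <- project_tilt_series(volume, angles_deg)
  for (a in seq_along(ts$angles_deg))
    ts$projections[, , a] <- add_noise_to_snr(
      ts$projections[, , a, drop = FALSE][, , 1L], target_snr,
      seed = seed + a - 1L)
  ts
}

# ---- projection geometry (shared with the recon module) -------------------

#' Flatten a volume (x, y, z) into an (x*z) x y matrix of slice columns.
#' @keywords internal
#' @noRd
vol_to_mat <- function(volume) {
  d <- dim(volume)
  m <- aperm(volume, c(1L, 3L, 2L))
  dim(m) <- c(d[1L] * d[3L], d[2L])
  m
}

#' Inverse of vol_to_mat.
#' @keywords internal
#' @noRd
mat_to_vol <- function(m, shape) {
  dim(m) <- c(shape[1L], shape[3L], shape[2L])
  aperm(m, c(1L, 3L, 2L))
}

#' Sparse projection operators, one per tilt angle
#'
#' Operator `a` maps the (x*z) x y flattened volume to the nx x ny detector:
#' rotation of each (x, z) plane by the tilt angle (bilinear interpolation)
#' followed by summation along z. Back projection is the exact transpose.
#'
#' @keywords internal
#' @noRd
projection_operators <- function(shape, angles_deg) {
  nx <- shape[1L]; nz <- shape[3L]
  cx <- (nx + 1) / 2; cz <- (nz + 1) / 2
  grid <- expand.grid(x = seq_len(nx), z = seq_len(nz))
  u <- grid$x - cx
  v <- grid$z - cz
  lapply(angles_deg, function(ang) {
    th <- ang * pi / 180
    xs <- cx + u * cos(th) + v * sin(th)
    zs <- cz - u * sin(th) + v * cos(th)
    x0 <- floor(xs); z0 <- floor(zs)
    fx <- xs - x0;   fz <- zs - z0
    rows <- integer(0); cols <- integer(0); vals <- numeric(0)
    for (corner in list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))) {
      xi <- x0 + corner[1L]
      zi <- z0 + corner[2L]
      w <- (if (corner[1L] == 1L) fx else 1 - fx) *
        (if (corner[2L] == 1L) fz else 1 - fz)
      ok <- xi >= 1 & xi <= nx & zi >= 1 & zi <= nz & w > 0
      rows <- c(rows, grid$x[ok])                 # detector column = output x
      cols <- c(cols, xi[ok] + (zi[ok] - 1L) * nx)  # flattened (x, z) source
      vals <- c(vals, w[ok])
    }
    Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                         dims = c(nx, nx * nz))
  })
}
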