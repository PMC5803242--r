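# Minimal parallel-beam reconstructors. Both share the sparse
# rotate-and-sum projector used to generate tilt series, and back projection
# is the literal matrix transpose, so the projector/back-projector pair is
# adjoint-consistent by construction.

#' Reconstruction configuration
#'
#' @param method `"wbp"` (ramp-filtered back projection) or `"sirt"`
#'   (simultaneous iterative reconstruction technique).
#' @param iterations SIRT iteration count (default 15).
#' @param relaxation SIRT relaxation factor in (0, 2) (default 1).
#' @param filter WBP weighting: `"ramp"` (default) or `"none"` (plain back
#'   projection, useful only for tests).
#' @param output_shape three integers; defaults to an `nx x ny x nx` volume
#'   inferred from the projections.
#' @return A list of class `recon_config`.
#' @export
recon_config <- function(method = c("wbp", "sirt"), iterations = 15L,
                         relaxation = 1, filter = c("ramp", "none"),
                         output_shape = NULL) {
  method <- match.arg(method)
  filter <- match.arg(filter)
  iterations <- as.integer(iterations)
  if (iterations < 1L) stopf("'iterations' must be >= 1")
  if (relaxation <= 0 || relaxation >= 2)
    stopf("'relaxation' must lie in (0, 2)")
  structure(list(method = method, iterations = iterations,
                 relaxation = relaxation, filter = filter,
                 output_shape = output_shape),
            class = "recon_config")
}

#' @keywords internal
#' @noRd
recon_shape <- function(ts, cfg) {
  d <- dim(ts$projections)
  shape <- cfg$output_shape
  if (is.null(shape)) shape <- c(d[1L], d[2L], d[1L])
  as.integer(shape)
}

#' Weighted back projection (WBP)
#'
#' Each projection is ramp-filtered along the detector axis perpendicular to
#' the tilt axis (1-D FFT weighting, zero-padded to avoid circular
#' artifacts) and back-projected over the tilt angles. Linear in the input.
#'
#' @param ts a [tilt_series()] with at least two projections.
#' @param cfg a [recon_config()].
#' @return Reconstructed 3-D array.
#' @export
wbp <- function(ts, cfg = recon_config("wbp")) {
  if (!inherits(ts, "tilt_series")) stopf("'ts' must be a tilt_series")
  d <- dim(ts$projections)
  if (d[3L] < 2L) stopf("WBP needs at least two projections")
  shape <- recon_shape(ts, cfg)
  ops <- projection_operators(shape, ts$angles_deg)
  acc <- matrix(0, shape[1L] * shape[3L], shape[2L])
  for (a in seq_len(d[3L])) {
    p <- ts$projections[, , a]
    if (cfg$filter == "ramp") p <- ramp_filter(p)
    acc <- acc + as.matrix(Matrix::t(ops[[a]]) %*% p)
  }
  mat_to_vol(acc * (pi / (2 * d[3L])), shape)
}

#' 1-D ramp filtering of a projection along the detector x axis
#' @keywords internal
#' @noRd
ramp_filter <- function(p, pad_factor = 2L) {
  nx <- nrow(p)
  len <- 2^ceiling(log2(pad_factor * nx))
  padded <- rbind(p, matrix(0, len - nx, ncol(p)))
  freq <- c(seq.int(0L, len %/% 2L), seq.int(-(len %/% 2L - 1L), -1L)) / len
  filt <- abs(freq)
  ft <- stats::mvfft(padded) * filt
  out <- Re(stats::mvfft(ft, inverse = TRUE)) / len
  out[seq_len(nx), , drop = FALSE]
}

#' Simultaneous iterative reconstruction technique (SIRT)
#'
#' Landweber-SIRT with row/column-sum normalization: starting from zero,
#' \deqn{x \leftarrow x + \lambda\, C \odot A^T (R \odot (b - A x))}
#' where R and C are the reciprocal row and column sums of the projector A
#' (the same operator used to generate tilt series; the adjoint is the exact
#' transpose). Iteration stops early with a warning if the reprojection
#' residual grows three iterations running.
#'
#' @inheritParams wbp
#' @param cfg a [recon_config()]; `iterations` and `relaxation` are used.
#' @return Reconstructed 3-D array.
#' @export
sirt <- function(ts, cfg = recon_config("sirt")) {
  if (!inherits(ts, "tilt_series")) stopf("'ts' must be a tilt_series")
  d <- dim(ts$projections)
  if (d[3L] < 2L) stopf("SIRT needs at least two projections")
  shape <- recon_shape(ts, cfg)
  ops <- projection_operators(shape, ts$angles_deg)
  na <- d[3L]
  nvox <- shape[1L] * shape[3L]
  ones_vol <- matrix(1, nvox, 1L)
  row_sums <- lapply(ops, function(op) {
    r <- as.numeric(op %*% ones_vol)
    ifelse(r > 1e-10, 1 / r, 0)
  })
  col_sum <- numeric(nvox)
  for (a in seq_len(na))
    col_sum <- col_sum + as.numeric(Matrix::t(ops[[a]]) %*% rep(1, shape[1L]))
  col_w <- ifelse(col_sum > 1e-10, 1 / col_sum, 0)
  x <- matrix(0, nvox, shape[2L])
  prev_res <- Inf
  grow <- 0L
  for (it in seq_len(cfg$iterations)) {
    corr <- matrix(0, nvox, shape[2L])
    res2 <- 0
    for (a in seq_len(na)) {
      r <- ts$projections[, , a] - as.matrix(ops[[a]] %*% x)
      res2 <- res2 + sum(r^2)
      corr <- corr + as.matrix(Matrix::t(ops[[a]]) %*% (r * row_sums[[a]]))
    }
    res <- sqrt(res2)
    if (res > prev_res) grow <- grow + 1L else grow <- 0L
    if (grow >= 3L) {
      warning(sprintf("SIRT residual grew 3 iterations running; stopped at iteration %d",
                      it), call. = FALSE)
      break
    }
    prev_res <- res
    x <- x + cfg$relaxation * (corr * col_w)
  }
  mat_to_vol(x, shape)
}

#' Reprojection residual norm of a reconstruction against a tilt series
#'
#' Utility for convergence monitoring and tests: the Frobenius norm of
#' `b - A x` where A is the shared projector.
#'
#' @param volume reconstructed 3-D array.
#' @param ts the measured [tilt_series()].
#' @return Non-negative scalar.
#' @export
reprojection_residual <- function(volume, ts) {
  rep_ts <- project_tilt_series(volume, ts$angles_deg)
  sqrt(sum((ts$projections - rep_ts$projections)^2))
}
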