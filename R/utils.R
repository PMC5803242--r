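# Internal array helpers shared by the transform, denoisers and simulators.

#' @keywords internal
#' @noRd
stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' Run code with a temporary RNG seed, restoring global RNG state afterwards.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stopf("'seed' must be a single finite number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Mirror (reflect, no edge repeat) index map: fold arbitrary integer
#' positions back into 1..n with period 2n-2.
#' @keywords internal
#' @noRd
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  m <- (i - 1L) %% (2L * n - 2L)
  ifelse(m >= n, 2L * n - 2L - m, m) + 1L
}

#' Extract an array slab along one axis by index vector (2-D or 3-D).
#' @keywords internal
#' @noRd
take_axis <- function(x, axis, idx) {
  nd <- length(dim(x))
  if (nd == 2L) {
    if (axis == 1L) x[idx, , drop = FALSE] else x[, idx, drop = FALSE]
  } else {
    switch(axis,
           x[idx, , , drop = FALSE],
           x[, idx, , drop = FALSE],
           x[, , idx, drop = FALSE])
  }
}

#' Circular convolution along one axis with dilated taps:
#' y[n] = sum_k taps[k] * x[n - offsets[k] * dilation]  (indices mod n).
#' @keywords internal
#' @noRd
conv_axis <- function(x, taps, offsets, axis, dilation = 1L) {
  n <- dim(x)[axis]
  out <- array(0, dim = dim(x))
  base <- seq_len(n)
  for (k in seq_along(taps)) {
    idx <- ((base - 1L - offsets[k] * dilation) %% n) + 1L
    out <- out + taps[k] * take_axis(x, axis, idx)
  }
  out
}

#' Mirror-pad an array by p voxels on every side of every axis.
#' @keywords internal
#' @noRd
pad_reflect <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  for (ax in seq_along(d)) {
    idx <- reflect_index(seq.int(1L - p, d[ax] + p), d[ax])
    x <- take_axis(x, ax, idx)
  }
  x
}

#' Crop the central region of a padded array back to `shape`.
#' @keywords internal
#' @noRd
crop_center <- function(x, p, shape) {
  if (p == 0L) return(x)
  for (ax in seq_along(shape)) x <- take_axis(x, ax, p + seq_len(shape[ax]))
  x
}

#' Separable box (moving-average) filter of odd edge length m, circular on
#' the array it is given (callers supply mirror context via padding).
#' @keywords internal
#' @noRd
box_filter <- function(x, m) {
  h <- m %/% 2L
  taps <- rep(1 / m, m)
  offs <- seq.int(-h, h)
  for (ax in seq_along(dim(x))) x <- conv_axis(x, taps, offs, ax)
  x
}

#' Validate a numeric 2-D/3-D array used as an image or volume.
#' @keywords internal
#' @noRd
check_image <- function(x, name = "image") {
  if (!is.array(x) || !is.numeric(x))
    stopf("'%s' must be a numeric array", name)
  nd <- length(dim(x))
  if (!nd %in% c(2L, 3L))
    stopf("'%s' must be 2-D or 3-D (got %d dimensions)", name, nd)
  if (anyNA(x) || any(!is.finite(x)))
    stopf("'%s' contains non-finite values", name)
  invisible(x)
}
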