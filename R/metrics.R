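# Evaluation of denoised or reconstructed data against a noise-free
# reference. All three measures accept an optional binary mask restricting
# evaluation to the object region; means are taken within the mask.

#' @keywords internal
#' @noRd
masked_values <- function(candidate, reference, mask, need_mask_voxels = 2L) {
  check_image(candidate, "candidate")
  check_image(reference, "reference")
  if (!identical(dim(candidate), dim(reference)))
    stopf("candidate and reference shapes differ")
  if (is.null(mask)) {
    sel <- rep(TRUE, length(reference))
  } else {
    if (!identical(dim(mask), dim(reference)))
      stopf("mask shape differs from the images")
    sel <- as.logical(mask)
    if (anyNA(sel)) stopf("mask contains NA")
  }
  n <- sum(sel)
  if (n < need_mask_voxels) stopf("mask selects fewer than %d voxels",
                                  need_mask_voxels)
  list(f = as.numeric(candidate)[sel], i = as.numeric(reference)[sel], n = n)
}

#' Variance-ratio signal-to-noise ratio against a noise-free reference
#'
#' \deqn{SNR = \frac{\sum_n (I(n) - \bar I)^2}{\sum_n (f(n) - I(n))^2}}
#' where `I` is the reference, `f` the candidate and the mean is taken
#' within the mask. Higher is better; an exact match yields `Inf` with a
#' warning.
#'
#' @param candidate denoised or reconstructed array.
#' @param reference noise-free array of the same shape.
#' @param mask optional binary array of the same shape.
#' @return Non-negative scalar (possibly `Inf`).
#' @export
snr <- function(candidate, reference, mask = NULL) {
  v <- masked_values(candidate, reference, mask)
  num <- sum((v$i - mean(v$i))^2)
  if (num == 0) stopf("reference is constant within the mask; SNR undefined")
  den <- sum((v$f - v$i)^2)
  if (den == 0) {
    warning("candidate equals reference within the mask; SNR is infinite",
            call. = FALSE)
    return(Inf)
  }
  num / den
}

#' Mean squared error against a noise-free reference
#'
#' \deqn{MSE = \frac{1}{N} \sum_n (f(n) - I(n))^2} over the mask.
#'
#' @inheritParams snr
#' @return Non-negative scalar.
#' @export
mse <- function(candidate, reference, mask = NULL) {
  v <- masked_values(candidate, reference, mask, need_mask_voxels = 1L)
  mean((v$f - v$i)^2)
}

#' Cross-correlation coefficient against a noise-free reference
#'
#' Pearson correlation of the mask-centered values; 1 for identical shapes
#' (up to a positive affine map), -1 for sign-inverted ones.
#'
#' @inheritParams snr
#' @return Scalar in \[-1, 1\].
#' @export
ccc <- function(candidate, reference, mask = NULL) {
  v <- masked_values(candidate, reference, mask)
  fc <- v$f - mean(v$f)
  ic <- v$i - mean(v$i)
  sf <- sum(fc^2)
  si <- sum(ic^2)
  if (sf == 0 || si == 0)
    stopf("zero variance within the mask; CCC undefined")
  sum(fc * ic) / sqrt(sf * si)
}

#' Full metrics report
#'
#' Computes SNR, MSE and CCC of a candidate against a reference in one call.
#'
#' @inheritParams snr
#' @return A list of class `metrics_report` with elements `snr`, `mse`,
#'   `ccc`, `n` (evaluated voxels) and `mask_used`.
#' @export
metrics_report <- function(candidate, reference, mask = NULL) {
  structure(list(snr = snr(candidate, reference, mask),
                 mse = mse(candidate, reference, mask),
                 ccc = ccc(candidate, reference, mask),
                 n = if (is.null(mask)) length(reference)
                     else sum(as.logical(mask)),
                 mask_used = !is.null(mask)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("SNR %.4g | MSE %.4g | CCC %.4f | n = %d voxels%s\n",
              x$snr, x$mse, x$ccc, x$n,
              if (x$mask_used) " (masked)" else ""))
  invisible(x)
}
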