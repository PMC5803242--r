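# Independent brute-force oracles. Everything here is deliberately written
# as plain loops / direct formula transcriptions, separate from the package's
# vectorized implementations.

# Circular 1-D convolution by explicit loop: y[n] = sum_k c[k] x[n - off[k]*dil]
oracle_conv1d <- function(x, taps, offsets, dilation = 1L) {
  n <- length(x)
  y <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (k in seq_along(taps)) {
      j <- ((i - 1L - offsets[k] * dilation) %% n) + 1L
      acc <- acc + taps[k] * x[j]
    }
    y[i] <- acc
  }
  y
}

# Single-axis a trous analysis of a 1-D signal (periodic), loop-based.
oracle_atrous_1d <- function(x, levels, bank) {
  details <- vector("list", levels)
  a <- x
  for (j in seq_len(levels)) {
    s <- 2L^(j - 1L)
    details[[j]] <- oracle_conv1d(a, bank$analysis_high$taps,
                                  bank$analysis_high$offsets, s)
    a <- oracle_conv1d(a, bank$analysis_low$taps,
                       bank$analysis_low$offsets, s)
  }
  list(details = details, approx = a)
}

# Apply a 1-D filter along one axis of a 2-D/3-D array using the loop conv.
oracle_conv_axis <- function(x, taps, offsets, axis, dilation = 1L) {
  d <- dim(x)
  out <- array(0, d)
  if (length(d) == 2L) {
    if (axis == 1L) for (c in seq_len(d[2L]))
      out[, c] <- oracle_conv1d(x[, c], taps, offsets, dilation)
    else for (r in seq_len(d[1L]))
      out[r, ] <- oracle_conv1d(x[r, ], taps, offsets, dilation)
  } else {
    if (axis == 1L) for (b in seq_len(d[3L])) for (c in seq_len(d[2L]))
      out[, c, b] <- oracle_conv1d(x[, c, b], taps, offsets, dilation)
    else if (axis == 2L) for (b in seq_len(d[3L])) for (r in seq_len(d[1L]))
      out[r, , b] <- oracle_conv1d(x[r, , b], taps, offsets, dilation)
    else for (c in seq_len(d[2L])) for (r in seq_len(d[1L]))
      out[r, c, ] <- oracle_conv1d(x[r, c, ], taps, offsets, dilation)
  }
  out
}

# Detail band (level j, dimension dd) by direct sequential application of the
# dilated analysis kernels (periodic), loop convolutions only.
oracle_band <- function(image, j, dd, bank) {
  a <- image
  nd <- length(dim(image))
  if (j > 1L) for (lev in seq_len(j - 1L)) {
    s <- 2L^(lev - 1L)
    for (ax in seq_len(nd))
      a <- oracle_conv_axis(a, bank$analysis_low$taps,
                            bank$analysis_low$offsets, ax, s)
  }
  s <- 2L^(j - 1L)
  if (dd > 1L) for (ax in seq_len(dd - 1L))
    a <- oracle_conv_axis(a, bank$analysis_low$taps,
                          bank$analysis_low$offsets, ax, s)
  oracle_conv_axis(a, bank$analysis_high$taps,
                   bank$analysis_high$offsets, dd, s)
}

# Moving-window mean over an m^D window, double loop, circular indexing.
oracle_box_mean <- function(x, m) {
  h <- m %/% 2L
  d <- dim(x)
  out <- array(0, d)
  if (length(d) == 2L) {
    for (i in seq_len(d[1L])) for (j in seq_len(d[2L])) {
      acc <- 0
      for (di in -h:h) for (dj in -h:h) {
        ii <- ((i - 1L + di) %% d[1L]) + 1L
        jj <- ((j - 1L + dj) %% d[2L]) + 1L
        acc <- acc + x[ii, jj]
      }
      out[i, j] <- acc / m^2
    }
  } else stop("oracle supports 2-D only")
  out
}

# Literal modulus -> direction -> normalize -> multiply -> project chain for
# cross-scale regularization on the bands of one level, given the (already
# final) coarser-level bands. 0/0 positions are masked to zero.
oracle_csr_level <- function(bands_j, bands_coarse) {
  mj <- sqrt(Reduce(`+`, lapply(bands_j, function(b) b^2)))
  mc <- sqrt(Reduce(`+`, lapply(bands_coarse, function(b) b^2)))
  mc_norm <- if (max(mc) == 0) mc else mc / max(mc)
  m_tilde <- mc_norm * mj
  lapply(bands_j, function(b) {
    w <- ifelse(mj > 0, b / mj, 0)   # unit direction component, 0/0 masked
    m_tilde * w
  })
}

# Metric formulas transcribed as explicit loops.
oracle_metrics <- function(f, i) {
  n <- length(f)
  fbar <- 0; ibar <- 0
  for (k in seq_len(n)) { fbar <- fbar + f[k]; ibar <- ibar + i[k] }
  fbar <- fbar / n; ibar <- ibar / n
  num <- 0; den <- 0; cfi <- 0; cff <- 0; cii <- 0
  for (k in seq_len(n)) {
    num <- num + (i[k] - ibar)^2
    den <- den + (f[k] - i[k])^2
    cfi <- cfi + (f[k] - fbar) * (i[k] - ibar)
    cff <- cff + (f[k] - fbar)^2
    cii <- cii + (i[k] - ibar)^2
  }
  list(snr = num / den, mse = den / n, ccc = cfi / sqrt(cff * cii))
}

# Small deterministic random arrays for property loops.
rand_image <- function(shape, seed) {
  set.seed(seed)
  array(stats::rnorm(prod(shape)), dim = shape)
}

# Shared small phantom for simulation-flavored unit tests.
small_phantom <- function(n = 32L) make_phantom(phantom_spec(rep(n, 3L)))

# Bridge to the internal window-mean engine so oracles can compare against it.
box_filter_for_test <- function(x, m) wavetomo:::box_filter(x, m)

# Seeded RNG draw for tests.
with_seed_for_test <- function(seed, code) { set.seed(seed); code }
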