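test_that("soft thresholding follows the three-case rule", {
  expect_equal(soft_threshold(c(-2, -0.5, 0, 0.5, 3), 1), c(-1, 0, 0, 0, 2))
  w <- rand_image(c(8L, 8L), seed = 1)
  expect_equal(soft_threshold(w, 0), w)                 # identity at 0
  expect_equal(soft_threshold(w, Inf), w * 0)           # full kill
  expect_equal(soft_threshold(w, max(abs(w)) + 1), w * 0)
  # magnitude never grows, sign preserved or zeroed
  out <- soft_threshold(w, 0.3)
  expect_true(all(abs(out) <= abs(w)))
  expect_true(all(out == 0 | sign(out) == sign(w)))
  # odd symmetry
  expect_equal(soft_threshold(-w, 0.3), -soft_threshold(w, 0.3))
  expect_error(soft_threshold(w, -1), "non-negative")
})

test_that("universal threshold evaluates sigma * sqrt(2 ln N)", {
  expect_equal(universal_threshold(1, 1), 0)
  expect_equal(universal_threshold(2, exp(2)), 4)
  expect_equal(universal_threshold(1, 65536), sqrt(2 * log(65536)))
  expect_error(universal_threshold(1, 0), "n")
  expect_error(universal_threshold(-1, 10), "sigma")
})

test_that("median noise estimator matches its definition on small samples", {
  expect_equal(median_sigma(rep(3, 10)), 3 / 0.6745)
  expect_equal(median_sigma(rep(-2, 5)), 2 / 0.6745)
  expect_equal(median_sigma(c(-1, 0, 1)), 1 / 0.6745)  # median of |W| = 1
  expect_equal(median_sigma(c(1, 3)), 2 / 0.6745)      # even count: midpoint
  expect_error(median_sigma(numeric(0)), "non-empty")
})

test_that("subband threshold is the noise-variance / subband-SD quotient", {
  expect_equal(subband_threshold(1, 2), 0.5)
  expect_equal(subband_threshold(0, 2), 0)        # noise-free band untouched
  expect_identical(subband_threshold(1, 0), Inf)  # degenerate band zeroed
  expect_error(subband_threshold(-1, 1), "non-negative")
})

test_that("w1 applies one global threshold to every band (flat oracle)", {
  x <- small_phantom(16L) + rand_image(c(16L, 16L, 16L), seed = 2)
  cfg <- denoise_config("w1", levels = 2L)
  p <- forward_ddwt(x, 2L)
  out <- apply_w1(p, cfg)
  lam <- universal_threshold(sd(as.numeric(x)), length(x))
  for (j in 1:2) for (d in 1:3) {
    w <- p$details[[j]][[d]]
    expect_equal(out$details[[j]][[d]], sign(w) * pmax(abs(w) - lam, 0))
  }
  expect_equal(out$approx, p$approx)  # approximation untouched
  # lambda = 0 is a no-op
  p0 <- apply_w1(p, denoise_config("w1", levels = 2L, lambda = 0))
  expect_equal(p0$details, p$details)
  # huge lambda leaves only the approximation
  pbig <- apply_w1(p, denoise_config("w1", levels = 2L, lambda = 1e9))
  expect_equal(inverse_ddwt(pbig),
               { pz <- p
                 for (j in 1:2) for (d in 1:3)
                   pz$details[[j]][[d]] <- pz$details[[j]][[d]] * 0
                 inverse_ddwt(pz) })
})

test_that("w2 zeroes the selected levels and soft-thresholds the rest subband-wise", {
  x <- small_phantom(16L) + 0.8 * rand_image(c(16L, 16L, 16L), seed = 3)
  p <- forward_ddwt(x, 3L)
  out <- apply_w2(p, denoise_config("w2", zero_levels = 1L))
  for (d in 1:3) expect_true(all(out$details[[1L]][[d]] == 0))
  for (j in 2:3) {
    pooled <- unlist(lapply(1:3, function(d) ddwt_band(p, j, d)))
    var_j <- median_sigma(pooled)^2
    for (d in 1:3) {
      lam <- subband_threshold(var_j, sd(as.numeric(ddwt_band(p, j, d))))
      expect_equal(out$details[[j]][[d]],
                   soft_threshold(p$details[[j]][[d]], lam))
    }
  }
  expect_equal(out$approx, p$approx)
  # non-expansiveness
  for (j in 1:3) for (d in 1:3)
    expect_true(all(abs(out$details[[j]][[d]]) <= abs(p$details[[j]][[d]])))
})

test_that("w2 degenerate configurations behave as documented", {
  x <- small_phantom(16L) + rand_image(c(16L, 16L, 16L), seed = 4)
  p <- forward_ddwt(x, 3L)
  # all levels zeroed: warning, output is the pure approximation
  expect_warning(out <- apply_w2(p, denoise_config("w2", zero_levels = 1:3)),
                 "approximation")
  pz <- p
  for (j in 1:3) for (d in 1:3) pz$details[[j]][[d]] <- pz$details[[j]][[d]] * 0
  expect_equal(inverse_ddwt(out), inverse_ddwt(pz))
  # no zeroing and zero noise variance: pyramid unchanged
  out2 <- apply_w2(p, denoise_config("w2", zero_levels = integer(0),
                                     noise_sigma = 0))
  expect_equal(out2$details, p$details)
  # zeroing is idempotent
  cfgz <- denoise_config("w2", zero_levels = c(1L, 2L), noise_sigma = 0)
  once <- apply_w2(p, cfgz)
  twice <- apply_w2(once, cfgz)
  expect_equal(twice$details, once$details)
})

test_that("w3 is the neighborhood mean (double-loop oracle) on modify levels", {
  # direct check of the window mean against a brute-force double loop
  b <- rand_image(c(9L, 9L), seed = 5)
  expect_lt(max(abs(box_filter_for_test(b, 5L) - oracle_box_mean(b, 5L))),
            1e-12)
  x <- rand_image(c(16L, 16L), seed = 6)
  p <- forward_ddwt(x, 3L)
  out <- apply_w3(p, denoise_config("w3", modify_levels = 1L))
  # modified band equals the box mean of the stored band; others untouched
  expect_equal(out$details[[1L]][[1L]],
               box_filter_for_test(p$details[[1L]][[1L]], 5L))
  expect_equal(out$details[[2L]], p$details[[2L]])
  expect_equal(out$approx, p$approx)
  # constant band is invariant under averaging
  pc <- forward_ddwt(array(2, c(16L, 16L)), 3L)
  outc <- apply_w3(pc, denoise_config("w3", modify_levels = 1L))
  expect_lt(max(abs(outc$details[[1L]][[1L]] - pc$details[[1L]][[1L]])), 1e-12)
  # impulse of height M^D spreads to 1 over the window
  imp <- array(0, c(15L, 15L)); imp[8L, 8L] <- 25
  expect_equal(sort(unique(as.numeric(round(oracle_box_mean(imp, 5L), 12)))),
               c(0, 1))
  expect_error(apply_w3(p, denoise_config("w3", neighborhood = 21L)),
               "neighborhood")
})

test_that("w4 fused update equals the literal modulus chain and is non-expansive", {
  x <- small_phantom(16L) + 0.5 * rand_image(c(16L, 16L, 16L), seed = 7)
  p <- forward_ddwt(x, 3L)
  out <- apply_w4(p, denoise_config("w4", modify_levels = c(1L, 2L)))
  # literal chain, coarse to fine
  lit2 <- oracle_csr_level(p$details[[2L]], p$details[[3L]])
  lit1 <- oracle_csr_level(p$details[[1L]], lit2)
  for (d in 1:3) {
    expect_lt(max(abs(out$details[[2L]][[d]] - lit2[[d]])), 1e-10)
    expect_lt(max(abs(out$details[[1L]][[d]] - lit1[[d]])), 1e-10)
    expect_true(all(abs(out$details[[1L]][[d]]) <=
                      abs(p$details[[1L]][[d]]) + 1e-15))
  }
  expect_equal(out$details[[3L]], p$details[[3L]])  # coarsest untouched
  expect_equal(out$approx, p$approx)
})

test_that("w4 handles constant and vanishing coarser moduli as documented", {
  p <- forward_ddwt(rand_image(c(16L, 16L), seed = 8), 3L)
  # constant positive coarser modulus: level-j bands unchanged
  q <- p
  q$details[[2L]][[1L]] <- array(3, dim(q$approx))
  q$details[[2L]][[2L]] <- array(4, dim(q$approx))  # modulus = 5 everywhere
  outq <- apply_w4(q, denoise_config("w4", modify_levels = 1L))
  expect_equal(outq$details[[1L]], q$details[[1L]])
  # identically zero coarser modulus: warning and zeroed bands
  z <- p
  z$details[[2L]][[1L]] <- z$details[[2L]][[1L]] * 0
  z$details[[2L]][[2L]] <- z$details[[2L]][[2L]] * 0
  expect_warning(outz <- apply_w4(z, denoise_config("w4", modify_levels = 1L)),
                 "zero")
  expect_true(all(outz$details[[1L]][[1L]] == 0))
  # zero modulus at a position zeroes that position
  q2 <- p
  q2$details[[2L]][[1L]][5L, 5L] <- 0
  q2$details[[2L]][[2L]][5L, 5L] <- 0
  outq2 <- apply_w4(q2, denoise_config("w4", modify_levels = 1L))
  # the padded band index matching source position (5,5)
  expect_equal(outq2$details[[1L]][[1L]][5L, 5L], 0)
  expect_error(denoise_config("w4", modify_levels = 3L), "coarser")
})

test_that("denoise_image round-trips under a no-op config and preserves shape", {
  x <- rand_image(c(32L, 32L), seed = 9)
  out <- denoise_image(x, denoise_config("w1", lambda = 0))
  expect_lt(max(abs(out - x)), 1e-8)
  v <- small_phantom(16L)
  for (s in c("w1", "w2", "w3", "w4"))
    expect_identical(dim(denoise_image(v + rand_image(dim(v), 10),
                                       denoise_config(s))), dim(v))
})

test_that("denoising is odd-symmetric: flipping the sign of the image flips the output", {
  x <- small_phantom(16L) + rand_image(c(16L, 16L, 16L), seed = 11)
  for (s in c("w1", "w2")) {
    cfg <- denoise_config(s)
    expect_equal(denoise_image(-x, cfg), -denoise_image(x, cfg),
                 tolerance = 1e-12)
  }
})

test_that("2-D slice mode equals looping the 2-D filter over slices", {
  v <- small_phantom(16L) + rand_image(c(16L, 16L, 16L), seed = 12)
  cfg <- denoise_config("w2", levels = 2L)
  out <- denoise_slices(v, cfg, slice_axis = 2L)
  for (i in c(1L, 8L, 16L))
    expect_equal(out[, i, ], denoise_image(v[, i, ], cfg))
})

test_that("the default configuration is the modified wavelet shrinkage filter", {
  cfg <- denoise_config()
  expect_identical(cfg$strategy, "w2")
  expect_identical(cfg$levels, 3L)
  expect_identical(cfg$zero_levels, 1L)
  expect_identical(cfg$threshold_mode, "subband")
})

test_that("config validation rejects bad inputs", {
  expect_error(denoise_config("w2", zero_levels = 5L), "1..3")
  expect_error(denoise_config("w3", neighborhood = 4L), "odd")
  expect_error(denoise_config("w3", neighborhood = 1L), "odd")
  expect_error(denoise_config(levels = 0L), "levels")
  expect_error(denoise_config("w2", noise_sigma = -1), "noise_sigma")
})
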