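---
title: "Wavelet shrinkage denoising for cryo-electron tomography: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet shrinkage denoising for cryo-ET: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wavetomo)
```

## The problem

Cryo-electron tomography (cryo-ET) images a vitrified specimen from a series
of tilt angles under a severely limited electron dose. The dose budget is
split across the whole tilt series, so individual projections — and the
tomogram reconstructed from them — are dominated by noise: variance-ratio
signal-to-noise ratios around 0.1 are typical. `wavetomo` implements a
family of wavelet-domain denoisers for this regime, together with everything
needed to evaluate them in a closed loop: a geometric phantom, an
SNR-calibrated noise generator, a parallel-beam tilt-series projector,
minimal WBP and SIRT reconstructors, and the SNR/MSE/CCC evaluation metrics.

The noise model is additive white Gaussian: the observed image is
\[ f(n) = I(n) + \varepsilon(n), \qquad \varepsilon \sim N(0, \sigma^2), \]
and the goal is an estimate of \(I\) from \(f\).

## The transform

All denoisers operate on the coefficients of an undecimated (redundant)
discrete dyadic wavelet transform, `forward_ddwt()`. Redundancy matters
here: a decimated transform is not translation invariant, and shift-variant
artifacts are unacceptable when the output feeds quantitative structural
analysis. The price is memory — every band has the shape of the input.

The filter bank (`default_spline_bank()`) is the quadratic-spline pair:
smoothing taps \((1,3,3,1)/8\) with unit DC gain, and a two-tap
first-difference wavelet filter \((1,-1)/2\) with zero mean. Spline wavelets
suit biological densities, which have smooth transitions rather than sharp
jumps. Dilation is "a trous": the level-\(j\) filters are the base taps with
\(2^{j-1}-1\) zeros between them, and nothing is ever downsampled. Three
decomposition levels are the default; fewer levels leave coarse-scale noise
untouched, and the study conditions this package reproduces found three
levels the useful depth for SNR-0.1 data.

Per level the decomposition produces one detail band per dimension,
gradient-like: within a level the axes are processed in order, and the
dimension-\(d\) band is high-pass along axis \(d\) and low-pass along the
axes already processed. This sequential form was chosen deliberately: it
admits an *exact* finite-impulse-response inverse. With 1-D synthesis
filters satisfying \(\tilde H H + \tilde G G = 1\) (the synthesis high-pass
has rational taps \((-1,-7,-22,-42,7,1)/32\), solved in closed form from
that identity), the per-axis analysis steps telescope and the reconstruction
is exact to machine precision. The alternative convention — low-pass along
*all* other axes in every detail band — has no FIR inverse of this form and
would have forced an approximate reconstruction. The per-level Euclidean
norm across the \(D\) bands (the wavelet modulus) is still a multiscale
gradient magnitude, which is what cross-scale regularization requires.

### Boundary handling

Two modes are provided. `"periodic"` uses circular convolution: perfect
reconstruction and *exact* shift invariance, but opposite faces of the
volume wrap into each other. `"symmetric"` (the default) mirror-extends the
image by a fixed margin of \(3(2^J - 1) + 1\) voxels — the cumulative reach
of the dilated filters — and runs the exact periodic algorithm on the
extended domain. Pyramids keep the extended bands internally (so the inverse
remains exact for arbitrary coefficient modifications) and expose
source-shaped crops through `ddwt_band()`. Band statistics used for
thresholds are always computed on the unpadded crop, so mirrored samples are
not double-counted.

## The four denoising strategies

All four modify only detail coefficients; the approximation band is never
touched, so the image's intensity scale is preserved (the low-pass chain has
unit DC gain).

**w1 — direct soft thresholding.** Every band, every level, one global
threshold: a user constant, or the universal threshold
\(\lambda = \sigma\sqrt{2\ln N}\) with \(\sigma\) the SD of the measured
data. Soft (not hard) thresholding throughout the package: hard thresholding
is discontinuous at \(\pm\lambda\) and produces abrupt artifacts when the
noise energy is large.

**w2 — modified shrinkage.** The recommended filter. First the bands at
`zero_levels` (default: level 1, the finest, which at SNR 0.1 is essentially
pure noise) are zeroed outright. Each remaining band is soft-thresholded
with its own subband-dependent threshold
\[ {}^d\lambda_j = \frac{\sigma_j^2}{{}^d\sigma_j}, \]
where \(\sigma_j\) is the level-\(j\) noise SD and \({}^d\sigma_j\) the
sample SD of the subband. When the noise SD is unknown it is estimated by
the robust median rule \(\hat\sigma_j = \mathrm{Median}(|W_j|)/0.6745\),
pooled over the level's \(D\) subbands; 0.6745 is the 0.75 quantile of the
standard normal, so the estimator is consistent under Gaussian noise and
insensitive to the sparse signal coefficients. Two readings of the
denominator exist in the shrinkage literature: the plain subband SD (used
here, as stated for this filter), or a BayesShrink-style signal SD
\(\sqrt{\max({}^d\sigma_j^2 - \sigma_j^2, 0)}\). The latter is available as
`signal_sd_adjust = TRUE` but is not the default; with it, thresholds grow
in noise-dominated bands, which is a different (if related) estimator than
the one this package implements by default. A subband with zero SD gets an
infinite threshold and is zeroed — a zero-variance band carries no signal,
and failing on one would make blank regions fatal.

**w3 — spatially adaptive thresholding.** Bands at `modify_levels` are
replaced by their moving-window mean over an \(M^D\) window
(default \(M = 5\), chosen empirically in the source study). This is linear
local averaging in the wavelet domain: the threshold effectively varies with
the local coefficient energy. Window context at band edges comes from the
transform's mirror extension.

**w4 — cross-scale regularization.** Noise is scale-local; real edges
persist across scales. For each level \(j\) in `modify_levels` (coarse to
fine, so that an already-modified level \(j+1\) is finished before it is
used), the coarser level's modulus is normalized to \([0,1]\) by its
maximum and multiplies the level-\(j\) coefficients pointwise. Working on
the modulus rather than on components preserves the local gradient
direction. The implementation fuses the modulus/direction decomposition and
the re-projection into \({}^d\tilde W_j = M^{norm}_{j+1}\cdot{}^dW_j\),
which is algebraically identical wherever the modulus is nonzero and
well-defined (zero) where it vanishes, removing the 0/0 case. If the
coarser modulus is identically zero the level is zeroed with a warning —
a blank image is valid input, not an error. Because \(M^{norm}\le 1\), w4
never amplifies a coefficient.

Strategy labels follow the `w2_1` / `w3_12` convention: the suffix lists
the levels zeroed (w2) or modified (w3/w4).

## Evaluation metrics

Against a noise-free reference \(I\), within an optional mask:
\[ \mathrm{SNR} = \frac{\sum (I - \bar I)^2}{\sum (f - I)^2}, \qquad
   \mathrm{MSE} = \frac{1}{N}\sum (f - I)^2, \qquad
   \mathrm{CCC} = \mathrm{corr}(f, I). \]
The reference mean \(\bar I\) is the scalar mask-mean — the only reading
that makes the numerator a variance. For a fixed reference and mask, SNR
and MSE are monotone transforms of the same error sum, so they always rank
candidates identically; CCC adds invariance to affine intensity changes,
which matters for reconstructions whose absolute scale is arbitrary (WBP's
scale depends on filter normalization). The default simulation mask is the
phantom support dilated by 2 voxels: evaluation is restricted to the object
region, where denoising quality actually matters, and the dilation keeps
edge behavior inside the mask.

## The simulation harness

**Phantom.** `make_phantom()` renders a deterministic 64³ multi-primitive
density map: a large low-contrast ellipsoid body, three spheres of
decreasing radius (6, 4, 2.5 voxels) and increasing contrast, a thin
vertical cylinder (radius 1.5) and a small box. The mixture is deliberate:
the large body tests smoothing, the small high-contrast primitives test
detail preservation, so over-aggressive level zeroing (w2_12, w2_123)
measurably hurts. All primitives lie inside the cylinder inscribed about
the vertical axis so projections conserve mass at every tilt angle.

**Noise.** `add_noise_to_snr()` adds i.i.d. Gaussian noise with
\(\sigma = \sqrt{\mathrm{Var}_{mask}(I)/\mathrm{SNR}_{target}}\). The
default target of 0.1 matches the noise level of real cryo-tomograms. The
generator is seed-deterministic and restores the caller's RNG state. What
the generator does *not* emulate: Poisson counting statistics, the contrast
transfer function, detector MTF, or dose-dependent damage — conclusions
from these simulations speak to additive-Gaussian robustness only.

**Tilt series.** `project_tilt_series()` computes parallel-beam line
integrals by rotating the volume about the vertical axis (bilinear
interpolation) and summing along the beam. The acquisition design is
\([-70^\circ, 70^\circ]\); tests and the demo pipeline use 3° steps
(47 projections) as a desk-scale version of the 1° acquisition — the
missing wedge is identical, only the angular sampling is coarser. Mass
conservation under rotation holds to <0.5% for objects inside the
inscribed cylinder (linear interpolation truncates only outside samples).

**Reconstruction.** The projector is assembled once per angle as a sparse
matrix, and back projection is its literal transpose, so the
projector/back-projector pair is adjoint-consistent by construction rather
than by tuning. WBP applies a 1-D FFT ramp along the detector axis
perpendicular to the tilt axis (zero-padded to the next power of two ≥ 2n
to avoid circular filtering artifacts). SIRT is the Landweber variant with
row/column-sum normalization,
\(x \leftarrow x + \lambda\, C \odot A^T(R \odot (b - Ax))\), default 15
iterations, relaxation 1 — declared defaults in the tradition of
electron-tomography SIRT implementations, not values inferred from any
reference software. A divergence guard stops early (with a warning) if the
reprojection residual grows three iterations running.

## Numerical choices and degenerate inputs

* All accumulation is in double precision regardless of input storage;
  MRC files are written as float32 (mode 2), the de-facto standard.
* Levels are 1-based, level 1 = finest. Volumes are `(x, y, z)` arrays with
  `y` the vertical tilt axis; 2-D slice-wise denoising defaults to slicing
  along `y`, matching how tilt images are oriented.
* Median: standard convention (midpoint of central order statistics for
  even counts), so threshold values are deterministic and testable.
* `soft_threshold(_, Inf)` returns a zero band; `snr()` of an exact match
  returns `Inf` with a warning; a constant reference is an error (the
  metric is uninformative, and silence would hide a broken pipeline).
* Zeroing all levels in w2 is a warning, not an error — the output is the
  pure approximation, which is a legitimate (if extreme) smoother.

## Problem sizes

The shipped tests and the demo pipeline run the full study at 64³ with 47
projections; unit tests use 16³–32³. These sizes were chosen so the whole
loop (generate → denoise → project → reconstruct → evaluate) completes in
about a minute on a laptop core while keeping the phantom large enough that
subband statistics (≥ 260k coefficients per band) are stable.

## Known limitations

* Gaussian noise only; no CTF, dose or detector physics.
* The reconstructors are minimal reference implementations: no fiducial
  alignment, no missing-wedge compensation beyond the angular range itself,
  no exact numerical equivalence with production packages is claimed.
* The spline bank is fixed; other wavelet families are out of scope.
* w3's window mean is a plain box filter; no data-driven window-size
  selection is attempted (5 is the study's empirical choice).

## A complete run

```{r demo, eval = FALSE}
phantom <- make_phantom(phantom_spec())
mask    <- phantom_mask(phantom)
noisy   <- add_noise_to_snr(phantom, target_snr = 0.1, seed = 1, mask = mask)

metrics_report(noisy, phantom, mask)
metrics_report(denoise_image(noisy, denoise_config("w2")), phantom, mask)

# the full comparison table: strategies x {volume, wbp, sirt}
df <- run_pipeline_demo(outdir = NULL, seed = 1)
```
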