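# wavetomo

Wavelet shrinkage denoising for cryo-electron tomography (cryo-ET), in R.

Cryo-ET produces three-dimensional views of unique biological objects from a
tilt series of electron-microscope projections, but the tolerable electron
dose is split across the whole series: individual images and the tomograms
reconstructed from them operate at variance-ratio signal-to-noise ratios
around 0.1, and fine structure drowns in noise. `wavetomo` denoises such
images and volumes in the coefficient domain of an **undecimated,
spline-based discrete dyadic wavelet transform (DDWT)** — redundant, hence
translation invariant — and ships the complete simulation loop needed to
evaluate a denoiser: phantom generation, SNR-calibrated Gaussian noise,
parallel-beam tilt-series projection, WBP and SIRT reconstruction, and
reference-based quality metrics.

The observed image is modeled as *f(n) = I(n) + ε(n)* with
*ε ~ N(0, σ²)*. Four coefficient-modification strategies are provided:

| label | strategy | coefficient rule |
|---|---|---|
| `w1` | direct soft thresholding | one global λ (constant or universal, λ = σ√(2 ln N)) on every detail band |
| `w2` | **modified shrinkage** | zero selected levels; soft-threshold the rest with the subband-dependent ᵈλⱼ = σⱼ² / ᵈσⱼ, σⱼ estimated by Median(\|Wⱼ\|)/0.6745 |
| `w3` | spatially adaptive | replace selected bands by their 5×5(×5) moving-window mean |
| `w4` | cross-scale regularization | attenuate level-j coefficients by the \[0,1\]-normalized wavelet modulus of level j+1 |

The default configuration — three decomposition levels, finest level zeroed,
subband-dependent threshold, soft thresholding, spline DDWT — is the
**modified wavelet shrinkage filter** (`w2_1`), the parameter set that best
trades noise suppression against detail preservation at SNR ≈ 0.1.

## Worked example

```r
library(wavetomo)

phantom <- make_phantom(phantom_spec())          # deterministic 64^3 phantom
mask    <- phantom_mask(phantom)                 # support dilated by 2 voxels
noisy   <- add_noise_to_snr(phantom, target_snr = 0.1, seed = 1, mask = mask)

metrics_report(noisy, phantom, mask)
#> SNR 0.09927 | MSE 4.665 | CCC 0.3049 | n = 30926 voxels (masked)

denoised <- denoise_image(noisy, denoise_config("w2"))   # w2_1 default
metrics_report(denoised, phantom, mask)
#> SNR 1.843 | MSE 0.2512 | CCC 0.6922 | n = 30926 voxels (masked)
```

The noisy volume measures SNR 0.099 — the calibrated generator hit its 0.1
target — and one pass of the modified wavelet shrinkage filter raises the
masked SNR eighteen-fold while cutting MSE from 4.67 to 0.25 and lifting the
cross-correlation with the noise-free phantom from 0.30 to 0.69.

The whole simulation study (every strategy, volume-domain and
per-projection denoising, WBP and SIRT reconstruction from a 47-angle
[−70°, 70°] tilt series) runs as one call and returns a metrics table:

```r
df <- run_pipeline_demo(outdir = "demo", seed = 1)
df[df$variant %in% c("noisy", "w2_1"), ]
#>   variant domain    snr   mse   ccc
#> 1   noisy volume 0.0993 4.665 0.305
#> 3    w2_1 volume 1.8431 0.251 0.692
#> 6   noisy    wbp 0.1569 2.952 0.177
#> 7   noisy   sirt 0.6280 0.737 0.456
#> 10   w2_1    wbp 0.8387 0.552 0.577
#> 11   w2_1   sirt 1.3996 0.331 0.616
```

Two field-typical orderings are visible: SIRT beats WBP on noisy data, and
denoising the tilt series before reconstruction improves both.

## Command line

A thin front-end over the same functions is installed at
`inst/scripts/wavetomo`:

```sh
Rscript inst/scripts/wavetomo simulate out/ --shape 64 --snr 0.1 --seed 1
Rscript inst/scripts/wavetomo denoise --strategy w2 --zero-levels 1 --mode 3d \
        out/phantom_noisy.mrc out/denoised.mrc
Rscript inst/scripts/wavetomo recon --method sirt out/tilt_series_noisy.mrc \
        out/tilt_series.tlt out/recon.mrc
Rscript inst/scripts/wavetomo metrics --mask support out/denoised.mrc out/phantom.mrc
```

I/O formats: MRC2014 volumes and stacks (mode 2 float32), single-image
TIFF, plain-text `.tlt` angle files, YAML denoising configs, CSV metric
tables.

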