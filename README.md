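# natimg

Reference-free image-quality assessment and training-data
regularization for super-resolution fluorescence microscopy, built on
natural-scene gradient statistics.

Deep-learning super-resolution models are evaluated with metrics (MAE,
PSNR, MS-SSIM, RMS contrast) that can be fooled: blurring a sparse
microscopy image and re-normalizing its intensity range *improves* all
of them while the image visibly gets worse.  `natimg` implements the
**naturalness factor**, a reference-free statistic that catches this.
The gradient and Laplacian distributions of natural images follow a
hyper-Laplace law with arctan-shaped CDF

    F(g; T) = 1/2 + atan(T·g)/π ,

with published natural-scene scale parameters T1pr = 0.38 (gradients)
and T2pr = 0.14 (Laplacian) on the 8-bit scale.  Fitting T1, T2 to an
image and comparing with the prior gives

    N_f = (1 − θ)·T1/T1pr + θ·T2/T2pr ,   θ = 0.5 by default.

N_f = 1 means natural-scene-like statistics (the target); N_f > 1
means too many small gradients (blur), N_f < 1 too many large ones
(noise, over-sharpening).  The package also provides:

* **naturalization** — a gradient-domain transform (histogram matching
  of the gradient components to the prior CDF, Poisson reintegration
  with a DCT solver, large-scale brightness anchoring) that moves an
  image's N_f toward 1, usable as a training-data preprocessing step;
* the full **metric suite** used alongside N_f: MAE, MSE, PSNR,
  multi-scale SSIM, RMS contrast, and image resolution by Fourier
  decorrelation analysis;
* a seeded **phantom generator** (filament- and dot-like structures
  with PSF blur and Poisson noise) so everything is testable without
  external data;
* **batch evaluation** with pairwise metric correlations
  (Pearson r, R², two-sided t-test with n − 2 dof).

## Worked example

```r
library(natimg)

img <- filament_phantom(phantom_spec("filament", seed = 3))
naturalness_factor(img)
#> <naturalness_result T1 = 0.3923, T2 = 0.2059, theta = 0.50, N_f = 1.251>

# blur + intensity renormalization: classic metrics improve, N_f and
# decorrelation resolution correctly get worse
blurred <- gaussian_blur_renormalize(img, kernel_px = 5L)
naturalness_factor(blurred)
#> <naturalness_result T1 = 0.3846, T2 = 0.2595, theta = 0.50, N_f = 1.433>
rms_contrast(img); rms_contrast(blurred)     # 662 -> 743 ("better"!)
decorrelation_curve(img)
#> <decorrelation_curve rc = 0.400, resolution = 161.50 nm>
decorrelation_curve(blurred)
#> <decorrelation_curve rc = 0.300, resolution = 215.33 nm>

# naturalization pulls the statistics back toward the prior
naturalness_factor(naturalize(blurred))
#> <naturalness_result T1 = 0.2761, T2 = 0.1436, theta = 0.50, N_f = 0.8763>
```

The N_f of 1.251 says this phantom is slightly smoother than a natural
scene; after the 5×5 blur it rises to 1.433 although contrast
"improved", and the decorrelation resolution degrades from 161 nm to
215 nm (pixel size 32.3 nm).  Naturalizing the blurred image brings
N_f back to 0.88.

A command-line interface is installed as `exec/natimg` with
subcommands `score`, `naturalize`, `metrics`, `blur`, `phantom` and
`correlate`; run it without arguments for usage.

## Package layout

* `R/gray-image.R` — image container, 8-bit conversion, TIFF/PNG I/O
* `R/gradient.R` — gradient/Laplacian fields, empirical CDFs,
  hyper-Laplace fits, prior estimation, naturalness factor
* `R/naturalize.R` — gradient histogram matching, DCT Poisson
  reintegration, naturalization
* `R/metrics.R` — MAE/MSE/PSNR, MS-SSIM, RMS contrast, decorrelation
  resolution, blur probe
* `R/phantoms.R` — seeded filament/dot phantom generator
* `R/evaluation.R` — batch scoring, metric correlations, reports
* `vignettes/naturalness-methods.Rmd` — model, numerical choices,
  design rationale, limitations
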