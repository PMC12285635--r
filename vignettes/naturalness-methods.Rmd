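---
title: "Gradient-statistics image quality: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gradient-statistics image quality: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(natimg)
```

## The model

Natural photographic scenes have intensity-gradient and Laplacian
distributions that follow a heavy-tailed hyper-Laplace law.  Its
cumulative form is arctan-shaped with a single scale parameter $T$:

$$F(g; T) = \tfrac12 + \frac{\arctan(T g)}{\pi}.$$

Large $T$ concentrates mass near zero (many small gradients, smooth
images); small $T$ produces heavy tails (many strong edges or noise).
The published natural-scene constants on the 8-bit intensity scale are
$T_1^{pr} = 0.38$ for first differences and $T_2^{pr} = 0.14$ for the
5-point Laplacian; `natimg` ships them as defaults
(`naturalness_prior()`) rather than re-estimating them from a photo
corpus.

For an image under test, `naturalness_factor()` converts to 8 bits
(min–max, so the statistic is invariant to intensity offset and gain),
computes forward differences $G_x, G_y$ and the Laplacian on the
interior valid region, fits $T_1$ to the two stacked gradient marginals
and $T_2$ to the Laplacian distribution by bounded least squares on the
CDF values, and reports

$$N_f = (1-\theta)\,\frac{T_1}{T_1^{pr}} + \theta\,\frac{T_2}{T_2^{pr}},
\qquad \theta \in [0, 1],\ \theta = 0.5 \text{ by default}.$$

$N_f = 1$ means natural-scene-like statistics.  $N_f > 1$: more small
gradients than natural (blur); $N_f < 1$: more large gradients
(sharpness or noise).  Because both the microscope image and the prior
are compared *after* 8-bit min–max conversion, $N_f$ is reference-free.

## Numerical choices

* **Fitting.**  The objective is the unweighted sum of squared
  deviations between the model CDF and the empirical CDF at its support
  points; the scalar search runs on $\log_{10} T \in [-4, 4]$ with
  `optimize()` (the objective is smooth and unimodal there).  A unit
  test checks the minimizer against a dense grid of $10^5$ log-spaced
  candidates.  Empirical CDFs with more than 20,000 support points are
  thinned to 20,000 evenly spaced quantiles first — a histogram
  approximation that changes fitted parameters by far less than the
  sampling noise at these sizes while bounding the fit cost.
* **Stencils.**  Gradients are one-sided forward differences; the
  Laplacian is the standard 5-point stencil, the simplest scheme
  consistent with forward differences.  All three fields are evaluated
  only where every stencil neighbour exists; no padding, so no
  fabricated edge gradients bias the distributions.
* **Degenerate inputs.**  Constant images (and all-zero gradient
  fields) raise a `degenerate_distribution` error instead of returning
  $T \to \infty$.
* **8-bit conversion.**  Linear min–max to $[0, 255]$ with
  round-half-to-even; a constant image maps to zero.  This makes the
  statistic independent of the original bit depth.

## Naturalization

`naturalize()` transforms an image so its gradient statistics approach
the prior.  One *pass* consists of:

1. **Histogram matching** (`match_gradient_histogram()`): each gradient
   component value $g$ maps monotonically to
   $F^{-1}(F_{emp}(g);\, T_1^{target})$ using the mid-rank empirical
   CDF, median-centred so that $g = 0$ stays at the target median 0.
   Mapped probabilities are clamped to $[F(-255), F(255)]$ because an
   8-bit image cannot contain larger gradients; without the clamp the
   arctan inverse diverges at extreme ranks.
2. **Reintegration** (`reintegrate()`): the least-squares image whose
   gradient best matches the modified field, i.e. the Neumann Poisson
   equation $\Delta I = \partial_x g_x + \partial_y g_y$, solved
   exactly by a DCT-II diagonalization.  For a consistent field this
   reproduces the source image to machine precision (tested), and the
   free constant is fixed at the reference mean.
3. **Range restoration.**  The matched field is heavy-tailed yet keeps
   the input's spatial sign coherence, so its raw integral drifts at
   large scales (a blurred input can reintegrate to several times the
   original intensity span).  Frequencies below roughly
   $1/\sigma_{anchor}$ (default $\sigma_{anchor} = 5$ px) are therefore
   re-anchored to the input — naturalization is meant to reshape
   fine-scale statistics, not large-scale brightness layout — and the
   result is clipped into the 8-bit working range.

Passes are applied greedily with step-size backtracking: a full pass
blends the matched field half-and-half with the original (an
already-natural image is then a near-fixed point); if a pass overshoots
$N_f = 1$, it is retried at damping 0.25 and 0.125, and the iteration
stops when no step reduces $|N_f - 1|$ (at most `max_passes` = 12 pass
evaluations).  The best iterate is returned, mapped back to the input's
own intensity range and bit depth.  This design emerged from three
observations on phantom corpora: a single undamped pass overshoots for
near-natural inputs (the per-component matching breaks integrability,
and the Poisson projection then shifts both orders), naive iteration
diverges, and a monotone value remap can never *create* high-frequency
content, so strongly blurred inputs converge to the target only
gradually.  Matching is first-order only: the second-order statistic is
dragged along (it is, in practice, the slower of the two), and solving
$\Delta I = L_{matched}$ directly was tested and rejected — the double
integration amplifies low-frequency error catastrophically.

Because gradients exist only on the interior region, outputs shrink by
a 1-pixel frame per side.  `reintegrate()` itself, as a standalone
operation, offers plain linear range rescaling (`preserve_range`); the
anchored restoration is specific to `naturalize()`.

## Metric suite

* **MAE / MSE / PSNR** follow their textbook definitions on the pixel
  values as given; `batch_evaluate()` min–max normalizes both images to
  $[0,1]$ independently before MAE/PSNR (unit peak for PSNR), the
  convention under which identical images score 0.  The CLI exposes
  `--mae-scale 8bit` to report MAE on the 0–255 scale instead.
  Identical images have no finite PSNR and are flagged rather than
  scored.
* **MS-SSIM**: five dyadic scales (2×2 mean pooling), 11-px Gaussian
  window with $\sigma = 1.5$, standard stabilizers for unit dynamic
  range, luminance at the coarsest scale only, contrast–structure at
  every scale, weights $\{0.0448, 0.2856, 0.3001, 0.2363, 0.1333\}$
  normalized to sum to one.  Inputs must be at least 176 px per side so
  the window fits at scale 5.
* **RMS contrast**: population standard deviation of the intensities.
* **Decorrelation resolution** (`decorrelation_curve()`): after a
  separable Hann taper over the outer 12 % of each dimension (applied
  around the image mean), the spectrum $I(k)$ and its phase-only
  normalization $I_n(k)$ are correlated under circular masks of 50
  radii $r \in (0, 1]$ in Nyquist-normalized frequency:
  $d(r) = \Re\{\sum I \bar I_n M\} / \sqrt{\sum |I|^2 \sum |I_n M|^2}$,
  DC excluded.  The maximizing radius $r_c$ (smallest on ties — the
  conservative choice) gives resolution $= 2 \cdot \text{pixel
  size}/r_c$, bounded below by twice the pixel size.  The masked sums
  are accumulated per radial bin, and a test verifies the result equals
  the explicit masked-spectrum correlation.
* **Blur probe** (`gaussian_blur_renormalize()`): square Gaussian
  kernel of odd size $k$ with $\sigma = k/6$, truncated to the kernel
  support, replicate boundaries.  Renormalizing the blurred image back
  to the original intensity range stretches the compressed histogram
  and *inflates* RMS contrast although the image got worse — the
  failure mode the naturalness factor detects.

## Synthetic phantoms

`filament_phantom()` renders smooth random curves (cubic splines
through 4–7 uniform control points, deposited with intensity
proportional to arc length and a 0.5-px anti-aliasing blur, stroke
width 1–2 px) emulating microtubule / F-actin structures;
`dot_phantom()` renders hard disks of radius 2–4 px emulating
clathrin-coated pits.  Both then share one camera pipeline: Gaussian
PSF blur, scaling so the *mean* signal photon count equals
`photon_budget` (photon levels for SIM data sets are quoted as image
averages; sparse structures then get realistically bright peaks),
constant background, Poisson shot noise, 16-bit container with a
32.3 nm default pixel pitch.  Defaults (256 px canvas, 12 filaments,
PSF $\sigma = 0.8$ px, 400 photons, background 10) were calibrated once
so that median $N_f$ of the filament class falls in the natural-like
window $[0.8, 1.3]$, mirroring the finding that filamentous
super-resolution images are near-natural while dot-like structures are
not (dense dot phantoms score far from 1).

What the phantoms do *not* emulate: structured-illumination
reconstruction artifacts, camera read noise, spatially varying PSFs,
sample autofluorescence, and the intensity statistics of real
endoplasmic-reticulum-like textures.  Passing tests on phantoms
therefore demonstrate correctness of the statistical machinery and the
qualitative directions (blur raises $N_f$ and worsens decorrelation
resolution; noise lowers $N_f$), not quantitative agreement with any
real instrument.

The degraded-pair generator draws a low-/high-resolution pair from one
object set with two PSF widths and independent shot noise — the
structure of matched wide-field / super-resolution acquisitions.

## Correlation analysis

`metric_correlations()` computes Pearson $r$ over every unordered pair
of {MS-SSIM, MAE, PSNR, Contrast, Resolution, $1 - N_f$} across a
corpus.  The naturalness factor enters as its deviation $1 - N_f$
because 1 is a target, not a monotone scale.  $R^2 = r^2$; p-values use
the two-sided Student-t transform with $n - 2$ degrees of freedom
(checked against `cor.test` and a permutation test).  Cells use
pairwise-complete observations with their own $n$; a zero-variance
metric marks its cells `degenerate-metric` instead of failing the whole
analysis.  Resolution enters in nanometers as computed.

## Problem sizes

The test suite and the acceptance script regenerate every input:
parameter recovery uses $10^6$ inverse-transform draws; the blur-
direction and correlation-sign analyses use 100 phantoms at 256 px;
the naturalization corpus uses 50 phantoms spanning $N_f \in [0.55,
2.8]$ via photon budgets 15–400 and blur kernels 3–13.  These sizes
keep every individual analysis in the seconds-to-a-few-minutes range
on one CPU while leaving the Monte-Carlo error far below the asserted
tolerances.

## Known limitations

* Naturalization cannot restore high-frequency content that blur has
  destroyed; strongly blurred inputs approach $N_f = 1$ over several
  damped passes but their texture remains smooth — the statistic is
  corrected, the lost detail is not recovered.
* The prior constants are for natural photographs; for structures that
  are legitimately non-natural (dot-like patterns), forcing $N_f = 1$
  is a model misspecification.
* The decorrelation implementation uses the fixed 50-radius global
  maximum; the refined local-maximum search over a filter bank used by
  some reference implementations is out of scope, so absolute
  resolution values should be compared within this package only.
* Whether the original naturalization procedure also equalizes the
  Laplacian histogram is undocumented; this package deliberately
  matches first order only (see above for the failed alternative).
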