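# Reference-based and reference-free image quality metrics: MAE, PSNR,
# multi-scale SSIM, RMS contrast, and decorrelation-analysis resolution.

pixels_of <- function(x) if (is_gray_image(x)) x$pixels else x

check_same_shape <- function(a, b) {
  if (!all(dim(a) == dim(b)))
    natimg_error("images must have identical shapes", "invalid_input")
}

# min-max normalization to [0, 1]; constant images map to zero
minmax01 <- function(p) {
  lo <- min(p); hi <- max(p)
  if (hi > lo) (p - lo) / (hi - lo) else p * 0
}

#' Mean absolute error between two images
#'
#' The averaged absolute pixel-wise difference over all pixels, computed
#' on the intensities as given.  Batch evaluation normalizes both images
#' to a common `[0, 1]` scale before calling this (see
#' [batch_evaluate()]).
#'
#' @param generated,reference images of identical shape.
#' @return Non-negative scalar; 0 for identical images.
#' @export
mae <- function(generated, reference) {
  a <- pixels_of(generated); b <- pixels_of(reference)
  check_same_shape(a, b)
  mean(abs(a - b))
}

#' Mean squared error between two images
#'
#' @inheritParams mae
#' @return Non-negative scalar.
#' @export
mse <- function(generated, reference) {
  a <- pixels_of(generated); b <- pixels_of(reference)
  check_same_shape(a, b)
  mean((a - b)^2)
}

#' Peak signal-to-noise ratio in decibels
#'
#' `10 log10(MAX_I^2 / MSE)`, where `MAX_I` is the maximum possible
#' pixel intensity of the representation (e.g. 65535 for 16-bit, 1 for
#' unit-normalized images).  PSNR = 0 means the noise power equals the
#' peak signal power; identical images (MSE = 0) have no finite PSNR and
#' raise an error.
#'
#' @inheritParams mae
#' @param max_intensity positive maximum representable intensity.
#' @return PSNR in dB.
#' @export
psnr <- function(generated, reference, max_intensity) {
  if (!is.numeric(max_intensity) || max_intensity <= 0)
    natimg_error("max_intensity must be positive", "invalid_input")
  m <- mse(generated, reference)
  if (m == 0)
    natimg_error("identical images: PSNR is undefined (MSE = 0)",
                 "undefined_psnr")
  10 * log10(max_intensity^2 / m)
}

#' Root-mean-square contrast
#'
#' The population standard deviation of the pixel intensities: a global,
#' structure-insensitive contrast measure.  Zero for a constant image;
#' invariant under constant intensity offsets.
#'
#' @param image a [gray_image()] or matrix.
#' @return Non-negative scalar.
#' @export
rms_contrast <- function(image) {
  p <- pixels_of(image)
  sqrt(mean((p - mean(p))^2))
}

# --- separable convolution with replicate (edge-clamp) boundaries -----------

conv_sep <- function(p, w) {
  r <- (length(w) - 1L) %/% 2L
  if (r == 0L) return(p * w[1L])
  m <- nrow(p); n <- ncol(p)
  out <- matrix(0, m, n)
  for (t in -r:r) {  # along rows (y)
    idx <- pmin(pmax(seq_len(m) + t, 1L), m)
    out <- out + w[t + r + 1L] * p[idx, , drop = FALSE]
  }
  p <- out
  out <- matrix(0, m, n)
  for (t in -r:r) {  # along columns (x)
    idx <- pmin(pmax(seq_len(n) + t, 1L), n)
    out <- out + w[t + r + 1L] * p[, idx, drop = FALSE]
  }
  out
}

gaussian_kernel_1d <- function(len, sigma) {
  r <- (len - 1L) / 2
  w <- dnorm(seq(-r, r), sd = max(sigma, 1e-12))
  w / sum(w)
}

# internal Gaussian blur by sigma with support truncated at ~3 sigma
gaussian_blur_sigma <- function(p, sigma) {
  if (sigma <= 0) return(p)
  len <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  conv_sep(p, gaussian_kernel_1d(len, sigma))
}

#' Gaussian blur with optional intensity-range renormalization
#'
#' Blurs with a square Gaussian kernel of the given odd pixel size
#' (sigma = kernel/6, truncated to the kernel support, replicate
#' boundaries).  With `renormalize`, the result is rescaled linearly to
#' the input's original `[min, max]`: blurring compresses intensities
#' into a narrower range, and stretching them back inflates the RMS
#' contrast even though the image got worse — the failure mode the
#' naturalness factor is designed to catch.
#'
#' @param image a [gray_image()] or matrix.
#' @param kernel_px positive odd kernel size in pixels; 1 is identity.
#' @param renormalize rescale output to the input's intensity range.
#' @return A blurred [gray_image()] at the input bit depth.
#' @export
gaussian_blur_renormalize <- function(image, kernel_px = 5L,
                                      renormalize = TRUE) {
  image <- as_gray_image(image)
  kernel_px <- as.integer(kernel_px)
  if (kernel_px < 1L || kernel_px %% 2L == 0L)
    natimg_error("kernel_px must be a positive odd integer", "invalid_input")
  if (kernel_px > min(dim(image$pixels)))
    natimg_error("kernel larger than the image", "invalid_input")
  p <- image$pixels
  if (kernel_px > 1L)
    p <- conv_sep(p, gaussian_kernel_1d(kernel_px, kernel_px / 6))
  if (renormalize) {
    lo <- min(image$pixels); hi <- max(image$pixels)
    blo <- min(p); bhi <- max(p)
    p <- if (bhi > blo) (p - blo) / (bhi - blo) * (hi - lo) + lo
    else p * 0 + lo
  }
  gray_image(p, bit_depth = image$bit_depth,
             pixel_size_nm = image$pixel_size_nm)
}

# --- multi-scale SSIM --------------------------------------------------------

# single-scale luminance and contrast-structure means with an 11-px
# Gaussian window (sigma 1.5); inputs on [0, 1], standard stabilizers
ssim_lcs <- function(x, y, C1 = 0.01^2, C2 = 0.03^2) {
  w <- gaussian_kernel_1d(11L, 1.5)
  mu_x <- conv_sep(x, w); mu_y <- conv_sep(y, w)
  sxx <- conv_sep(x * x, w) - mu_x^2
  syy <- conv_sep(y * y, w) - mu_y^2
  sxy <- conv_sep(x * y, w) - mu_x * mu_y
  l <- (2 * mu_x * mu_y + C1) / (mu_x^2 + mu_y^2 + C1)
  cs <- (2 * sxy + C2) / (sxx + syy + C2)
  list(l = mean(l), cs = mean(cs))
}

downsample2 <- function(p) {
  m <- 2L * (nrow(p) %/% 2L); n <- 2L * (ncol(p) %/% 2L)
  p <- p[seq_len(m), seq_len(n), drop = FALSE]
  (p[seq(1L, m, 2L), seq(1L, n, 2L)] + p[seq(2L, m, 2L), seq(1L, n, 2L)] +
     p[seq(1L, m, 2L), seq(2L, n, 2L)] + p[seq(2L, m, 2L), seq(2L, n, 2L)]) / 4
}

#' Multi-scale structural similarity index (MS-SSIM)
#'
#' Weighted product of per-scale SSIM terms over 5 dyadic scales:
#' the luminance term enters at the coarsest scale only, the combined
#' contrast-structure term at every scale, with the standard weights
#' `{0.0448, 0.2856, 0.3001, 0.2363, 0.1333}` normalized to sum to one.
#' Both images are min-max normalized to `[0, 1]` independently; scales
#' are produced by 2x2 mean pooling.  Images must be at least 176 px per
#' side so the 11-px window fits at the fifth scale.
#'
#' @inheritParams mae
#' @return Scalar in `[0, 1]`; 1 for identical images.
#' @export
ms_ssim <- function(generated, reference) {
  a <- pixels_of(generated); b <- pixels_of(reference)
  check_same_shape(a, b)
  if (min(dim(a)) < 176L)
    natimg_error("images must be at least 176 px per side for 5-scale MS-SSIM",
                 "invalid_input")
  x <- minmax01(a); y <- minmax01(b)
  w <- c(0.0448, 0.2856, 0.3001, 0.2363, 0.1333)
  w <- w / sum(w)
  M <- length(w)
  cs_means <- numeric(M)
  l_final <- NA_real_
  for (j in seq_len(M)) {
    sc <- ssim_lcs(x, y)
    cs_means[j] <- sc$cs
    if (j == M) l_final <- sc$l
    if (j < M) { x <- downsample2(x); y <- downsample2(y) }
  }
  terms <- pmax(c(cs_means, l_final), 0)
  val <- prod(terms^c(w, w[M]))
  min(max(val, 0), 1)
}

# --- decorrelation-analysis resolution ---------------------------------------

# separable raised-cosine (Hann) taper over the outer `frac` of each
# dimension, applied around the image mean
apodize_edges <- function(p, frac = 0.12) {
  taper <- function(n) {
    L <- max(1L, round(frac * n))
    w <- rep(1, n)
    ramp <- 0.5 - 0.5 * cos(pi * (seq_len(L) - 0.5) / L)
    w[seq_len(L)] <- ramp
    w[n + 1L - seq_len(L)] <- ramp
    w
  }
  mu <- mean(p)
  W <- outer(taper(nrow(p)), taper(ncol(p)))
  mu + (p - mu) * W
}

#' Image resolution by Fourier decorrelation analysis
#'
#' Reference-free resolution estimation: after edge apodization, the
#' image spectrum `I(k)` and its phase-only normalization
#' `I_n(k) = I(k)/|I(k)|` are cross-correlated under circular low-pass
#' masks `M(k; r)` of 50 uniformly spaced normalized radii in `(0, 1]`
#' (1 = Nyquist):
#' \deqn{d(r) = \Re\{\sum_k I \bar I_n M\} /
#'   \sqrt{\sum_k |I|^2 \sum_k |I_n M|^2}}
#' The zero-frequency bin is excluded.  The radius `r_c` maximizing
#' `d(r)` (smallest radius on ties) sets the resolution estimate
#' `2 * pixel_size / r_c`.
#'
#' @param image a [gray_image()] with `pixel_size_nm` set, at least
#'   64 px per side; non-square images are center-cropped to a square.
#' @return A `decorrelation_curve` with `radii`, `d_values`, `rc`,
#'   `resolution_nm`.
#' @export
decorrelation_curve <- function(image) {
  image <- as_gray_image(image)
  if (is.null(image$pixel_size_nm))
    natimg_error("pixel_size_nm is required for a resolution estimate",
                 "missing_metadata")
  p <- image$pixels
  if (all(p == 0))
    natimg_error("all-zero image has no spectrum to analyze",
                 "degenerate_input")
  n <- min(dim(p))
  if (n < 64L)
    natimg_error("image must be at least 64 px per side", "invalid_input")
  r0 <- (nrow(p) - n) %/% 2L; c0 <- (ncol(p) - n) %/% 2L
  p <- p[r0 + seq_len(n), c0 + seq_len(n)]

  Fk <- fft(apodize_edges(p))
  # normalized frequencies: 1 at Nyquist along each axis
  k1 <- (c(0:(n %/% 2L), -((n - n %/% 2L - 1L):1L))) / (n / 2)
  rho <- sqrt(outer(k1^2, k1^2, `+`))
  Fk[1L, 1L] <- 0  # exclude the DC bin
  magF <- Mod(Fk)
  nonzero <- magF > 0

  nradii <- 50L
  radii <- seq_len(nradii) / nradii
  # bin each frequency by the smallest mask radius containing it
  bin <- ceiling(pmax(rho, .Machine$double.eps) * nradii)
  inband <- nonzero & bin <= nradii
  num_by_bin <- rep(0, nradii)      # sum over bin of |I| = Re(I conj(I_n))
  cnt_by_bin <- rep(0, nradii)      # sum over bin of |I_n|^2 (0/1)
  tb <- tapply(magF[inband], bin[inband], sum)
  num_by_bin[as.integer(names(tb))] <- tb
  tc <- tapply(rep(1, sum(inband)), bin[inband], sum)
  cnt_by_bin[as.integer(names(tc))] <- tc

  total_power <- sum(magF^2)
  num <- cumsum(num_by_bin)
  den <- sqrt(total_power * cumsum(cnt_by_bin))
  d <- ifelse(den > 0, num / den, 0)

  rc <- radii[which.max(d)]  # which.max: first (smallest radius) on ties
  structure(
    list(radii = radii, d_values = d, rc = rc,
         resolution_nm = 2 * image$pixel_size_nm / rc),
    class = "decorrelation_curve")
}

#' @export
print.decorrelation_curve <- function(x, ...) {
  cat(sprintf("<decorrelation_curve rc = %.3f, resolution = %.2f nm>\n",
              x$rc, x$resolution_nm))
  invisible(x)
}
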