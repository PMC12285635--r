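#' Forward-difference gradient and Laplacian fields
#'
#' Computes the per-pixel forward differences
#' `gx(x, y) = I(x + 1, y) - I(x, y)` and
#' `gy(x, y) = I(x, y + 1) - I(x, y)` together with the 5-point-stencil
#' Laplacian `I(x+1,y) + I(x-1,y) + I(x,y+1) + I(x,y-1) - 4 I(x,y)`.
#' All three rasters are evaluated only on the interior valid region
#' (boundary rows and columns excluded), so no padding ever fabricates
#' edge gradients that would bias the gradient statistics.
#'
#' @param image a [gray_image()] or numeric matrix, at least 3 x 3.
#' @return A `gradient_field` with components `gx`, `gy`, `laplacian`,
#'   each a matrix of size `(nrow - 2) x (ncol - 2)`.
#' @examples
#' ramp <- matrix(rep(1:8, each = 8), 8, 8)  # I(x, y) = x
#' f <- gradient_field(ramp)
#' stopifnot(all(f$gx == 1), all(f$gy == 0), all(f$laplacian == 0))
#' @export
gradient_field <- function(image) {
  p <- if (is_gray_image(image)) image$pixels else image
  if (!is.matrix(p) || !is.numeric(p))
    natimg_error("expected a gray_image or numeric matrix", "invalid_input")
  m <- nrow(p); n <- ncol(p)
  if (m < 3L || n < 3L)
    natimg_error("image must be at least 3 x 3 for gradient fields",
                 "invalid_input")
  r <- 2:(m - 1L); cl <- 2:(n - 1L)
  gx <- p[r, cl + 1L] - p[r, cl]
  gy <- p[r + 1L, cl] - p[r, cl]
  lap <- p[r, cl + 1L] + p[r, cl - 1L] + p[r + 1L, cl] + p[r - 1L, cl] -
    4 * p[r, cl]
  # drop = FALSE not needed: m, n >= 3 guarantees matrices unless 3x3
  if (m == 3L || n == 3L) {
    gx <- matrix(gx, m - 2L, n - 2L)
    gy <- matrix(gy, m - 2L, n - 2L)
    lap <- matrix(lap, m - 2L, n - 2L)
  }
  structure(list(gx = gx, gy = gy, laplacian = lap),
            class = "gradient_field")
}

#' Empirical cumulative distribution of a sample
#'
#' The gradient and Laplacian distributions are approximated by their
#' normalized discrete histograms; this returns the right-continuous
#' empirical CDF evaluated at the sorted unique sample values.
#'
#' @param samples numeric vector of at least 100 finite values.
#' @return An `empirical_cumulative` with fields `support` (sorted unique
#'   values), `cdf` (non-decreasing, last element 1) and `n`.
#' @export
empirical_cumulative <- function(samples) {
  samples <- as.numeric(samples)
  if (length(samples) < 100L)
    natimg_error("need at least 100 samples for an empirical CDF",
                 "insufficient_data")
  if (!all(is.finite(samples)))
    natimg_error("samples must be finite", "invalid_input")
  r <- rle(sort(samples))
  structure(
    list(support = r$values,
         cdf = cumsum(r$lengths) / length(samples),
         n = length(samples)),
    class = "empirical_cumulative")
}

is_empirical_cumulative <- function(x) inherits(x, "empirical_cumulative")

# --- hyper-Laplace cumulative model -----------------------------------------
# F(g; T) = 1/2 + atan(T g) / pi  (first order; the Laplacian form is the
# same arctan shape).  Heavy-tailed: larger T puts more mass near zero.

hl_cdf <- function(g, t) 0.5 + atan(t * g) / pi

hl_quantile <- function(u, t) tan(pi * (u - 0.5)) / t

#' Inverse-transform sampling from the hyper-Laplace cumulative model
#'
#' Draws i.i.d. values whose CDF is `1/2 + atan(T x)/pi`.  Used for
#' parameter-recovery checks of the fitting operations.
#'
#' @param n number of draws.
#' @param t positive scale parameter T.
#' @return Numeric vector of length `n`.
#' @export
sample_hyper_laplace <- function(n, t) {
  stopifnot(t > 0, n >= 1)
  hl_quantile(runif(n), t)
}

# Least-squares fit of T to one or more stacked empirical CDFs.
# Bounded scalar search on T in [1e-4, 1e4], performed on log10(T) where
# the objective is smooth and unimodal.  Empirical CDFs with very many
# support points are thinned to evenly spaced quantiles first (histogram
# approximation); the objective is unweighted least squares on the CDF
# values.
fit_hyper_laplace <- function(support, cdf, max_points = 20000L) {
  keep <- is.finite(support)
  support <- support[keep]; cdf <- cdf[keep]
  if (length(support) == 0L || all(support == 0))
    natimg_error("degenerate (all-zero) distribution: cannot fit T",
                 "degenerate_distribution")
  if (length(support) > max_points) {
    idx <- unique(round(seq(1L, length(support), length.out = max_points)))
    support <- support[idx]; cdf <- cdf[idx]
  }
  obj <- function(lt) {
    t <- 10^lt
    sum((hl_cdf(support, t) - cdf)^2)
  }
  opt <- optimize(obj, interval = c(-4, 4), tol = 1e-10)
  list(t = 10^opt$minimum, fit_residual = opt$objective)
}

new_hyper_laplace_params <- function(t, order, fit_residual) {
  structure(list(t = t, order = order, fit_residual = fit_residual),
            class = "hyper_laplace_params")
}

#' @export
print.hyper_laplace_params <- function(x, ...) {
  cat(sprintf("<hyper_laplace_params %s-order: T = %.6g (residual %.3g)>\n",
              x$order, x$t, x$fit_residual))
  invisible(x)
}

#' Fit the first-order parameter T1 to cumulative gradient distributions
#'
#' The model cumulative gradient distribution factorizes into identical
#' arctan-form marginals sharing one scale T1, so the two empirical
#' marginal CDFs (for the x- and y-gradient components) are stacked and
#' a single T1 is fitted by bounded least squares on the CDF values.
#'
#' @param gx_cdf,gy_cdf [empirical_cumulative()] objects for the two
#'   gradient components.
#' @return A `hyper_laplace_params` with `order = "first"`.
#' @export
fit_cgd_param <- function(gx_cdf, gy_cdf) {
  stopifnot(is_empirical_cumulative(gx_cdf), is_empirical_cumulative(gy_cdf))
  fit <- fit_hyper_laplace(c(gx_cdf$support, gy_cdf$support),
                           c(gx_cdf$cdf, gy_cdf$cdf))
  new_hyper_laplace_params(fit$t, "first", fit$fit_residual)
}

#' Fit the second-order parameter T2 to a cumulative Laplacian distribution
#'
#' @param lap_cdf [empirical_cumulative()] of the Laplacian samples.
#' @return A `hyper_laplace_params` with `order = "second"`.
#' @export
fit_cld_param <- function(lap_cdf) {
  stopifnot(is_empirical_cumulative(lap_cdf))
  fit <- fit_hyper_laplace(lap_cdf$support, lap_cdf$cdf)
  new_hyper_laplace_params(fit$t, "second", fit$fit_residual)
}

# Full per-image parameter pipeline: 8-bit conversion, interior gradient /
# Laplacian fields, empirical CDFs, bounded least-squares fits.
fit_image_params <- function(image) {
  img8 <- to_gray8(as_gray_image(image))
  f <- gradient_field(img8)
  if (all(f$gx == 0) && all(f$gy == 0))
    natimg_error("constant image: gradient distribution is degenerate",
                 "degenerate_distribution")
  t1 <- fit_cgd_param(empirical_cumulative(as.vector(f$gx)),
                      empirical_cumulative(as.vector(f$gy)))
  t2 <- fit_cld_param(empirical_cumulative(as.vector(f$laplacian)))
  list(t1 = t1$t, t2 = t2$t,
       t1_residual = t1$fit_residual, t2_residual = t2$fit_residual)
}

#' Natural-scene prior parameters
#'
#' The published natural-scene constants are T1 = 0.38 for the gradient
#' distribution and T2 = 0.14 for the Laplacian distribution, estimated
#' from a large corpus of 8-bit natural photographs.
#'
#' @param t1_prior,t2_prior positive prior scale parameters.
#' @return A `naturalness_prior`.
#' @export
naturalness_prior <- function(t1_prior = 0.38, t2_prior = 0.14) {
  if (!is.numeric(t1_prior) || t1_prior <= 0 ||
      !is.numeric(t2_prior) || t2_prior <= 0)
    natimg_error("prior parameters must be strictly positive",
                 "invalid_input")
  structure(list(t1_prior = as.numeric(t1_prior),
                 t2_prior = as.numeric(t2_prior)),
            class = "naturalness_prior")
}

#' Estimate a naturalness prior from a set of images
#'
#' Fits (T1, T2) per image (after 8-bit conversion) and averages them
#' arithmetically across images.
#'
#' @param images a list of [gray_image()] objects (or matrices).
#' @return A [naturalness_prior()].
#' @export
estimate_prior <- function(images) {
  if (!is.list(images) || length(images) == 0L)
    natimg_error("need at least one image to estimate a prior",
                 "invalid_input")
  fits <- lapply(images, fit_image_params)
  naturalness_prior(
    t1_prior = mean(vapply(fits, `[[`, numeric(1), "t1")),
    t2_prior = mean(vapply(fits, `[[`, numeric(1), "t2")))
}

#' Naturalness factor of an image
#'
#' Converts the image to 8 bits, fits the first- and second-order
#' hyper-Laplace parameters (T1, T2) to its gradient and Laplacian
#' statistics, and forms
#' \deqn{N_f = (1 - \theta)\,T_1/T_1^{pr} + \theta\,T_2/T_2^{pr}}
#' with weight `theta` between the first- and second-order terms.
#' N_f = 1 means the image's gradient statistics match natural scenes;
#' N_f > 1 means more small gradients (e.g. blurred images), N_f < 1
#' more large gradients (e.g. sharp or noisy images).
#'
#' @param image a [gray_image()] or numeric matrix.
#' @param prior a [naturalness_prior()]; defaults to the published
#'   natural-scene constants (0.38, 0.14).
#' @param theta weight in `[0, 1]` between first- and second-order
#'   statistics; default 0.5.
#' @return A `naturalness_result` with fields `t1`, `t2`, `theta`, `nf`.
#' @examples
#' img <- filament_phantom(phantom_spec("filament", seed = 1))
#' naturalness_factor(img)$nf
#' @export
naturalness_factor <- function(image, prior = naturalness_prior(),
                               theta = 0.5) {
  stopifnot(inherits(prior, "naturalness_prior"))
  if (!is.numeric(theta) || length(theta) != 1L || theta < 0 || theta > 1)
    natimg_error("theta must be a scalar in [0, 1]", "invalid_input")
  fit <- fit_image_params(image)
  nf <- (1 - theta) * fit$t1 / prior$t1_prior +
    theta * fit$t2 / prior$t2_prior
  structure(list(t1 = fit$t1, t2 = fit$t2, theta = theta, nf = nf,
                 prior = prior),
            class = "naturalness_result")
}

#' @export
print.naturalness_result <- function(x, ...) {
  cat(sprintf(
    "<naturalness_result T1 = %.4g, T2 = %.4g, theta = %.2f, N_f = %.4g>\n",
    x$t1, x$t2, x$theta, x$nf))
  invisible(x)
}
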