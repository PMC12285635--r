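# Seeded synthetic microscopy phantoms: filamentous (microtubule /
# F-actin-like) curves and dot-like (clathrin-coated-pit-like) disks,
# rendered through a Gaussian PSF with Poisson shot noise.  Pure
# functions of (spec, seed): regeneration is bit-exact.

#' Specification of a synthetic phantom
#'
#' @param kind "filament" or "dots".
#' @param size_px canvas side length in pixels, at least 64; default 256
#'   (the usual training crop size for super-resolution models).
#' @param n_objects number of curves or disks; defaults 12 (filament) /
#'   60 (dots).
#' @param psf_sigma_px Gaussian point-spread-function sigma in pixels
#'   (>= 0); default 0.8, a near-diffraction-limited high-NA PSF at the
#'   default 32.3 nm pixel pitch.
#' @param photon_budget expected photon count of the brightest structure
#'   (Poisson noise scale); default 400, a mid-range signal level for
#'   structured-illumination raw data.
#' @param background constant background photon level; default 10.
#' @param seed integer seed; the generator is a pure function of the
#'   spec including this seed.
#' @param poisson_noise draw Poisson shot noise (default TRUE); FALSE
#'   returns the noise-free expected intensity.
#' @return A `phantom_spec`.
#' @export
phantom_spec <- function(kind = c("filament", "dots"), size_px = 256L,
                         n_objects = NULL, psf_sigma_px = 0.8,
                         photon_budget = 400, background = 10,
                         seed = 0L, poisson_noise = TRUE) {
  kind <- match.arg(kind)
  size_px <- as.integer(size_px)
  if (size_px < 64L)
    natimg_error("size_px must be at least 64", "invalid_input")
  if (psf_sigma_px < 0)
    natimg_error("psf_sigma_px must be non-negative", "invalid_input")
  if (photon_budget <= 0)
    natimg_error("photon_budget must be positive", "invalid_input")
  if (background < 0)
    natimg_error("background must be non-negative", "invalid_input")
  n_objects <- as.integer(n_objects %||%
                            if (kind == "filament") 12L else 60L)
  if (n_objects < 0L)
    natimg_error("n_objects must be non-negative", "invalid_input")
  structure(list(kind = kind, size_px = size_px, n_objects = n_objects,
                 psf_sigma_px = psf_sigma_px,
                 photon_budget = photon_budget,
                 background = background, seed = as.integer(seed),
                 poisson_noise = isTRUE(poisson_noise)),
            class = "phantom_spec")
}

# bilinear deposition of weighted points into a canvas
splat_points <- function(canvas, x, y, w) {
  n <- nrow(canvas)
  ix <- floor(x); iy <- floor(y)
  fx <- x - ix; fy <- y - iy
  for (k in 1:4) {
    dx <- c(0L, 1L, 0L, 1L)[k]; dy <- c(0L, 0L, 1L, 1L)[k]
    wx <- if (dx == 0L) 1 - fx else fx
    wy <- if (dy == 0L) 1 - fy else fy
    i <- iy + dy; j <- ix + dx
    keep <- i >= 1 & i <= n & j >= 1 & j <= n
    if (!any(keep)) next
    lin <- (j[keep] - 1) * n + i[keep]
    add <- rowsum(w[keep] * wx[keep] * wy[keep], lin)
    canvas[as.numeric(rownames(add))] <-
      canvas[as.numeric(rownames(add))] + add[, 1L]
  }
  canvas
}

# smooth random curves: cubic splines through uniform control points,
# deposited with unit intensity per unit arc length and a ~1.5 px
# anti-aliasing blur
render_filaments <- function(size, n_objects) {
  canvas <- matrix(0, size, size)
  for (i in seq_len(n_objects)) {
    ncp <- sample(4:7, 1L)
    cx <- runif(ncp, 1, size)
    cy <- runif(ncp, 1, size)
    tt <- seq_len(ncp)
    dense <- seq(1, ncp, length.out = 24L * size %/% 8L)
    px <- spline(tt, cx, xout = dense)$y
    py <- spline(tt, cy, xout = dense)$y
    seg <- sqrt(diff(px)^2 + diff(py)^2)
    w <- c(seg[1L], seg)  # intensity proportional to local arc length
    canvas <- splat_points(canvas, px, py, w)
  }
  if (n_objects > 0L) canvas <- gaussian_blur_sigma(canvas, 0.5)
  canvas
}

# hard (binary) disks of radius 2-4 px; overlaps take the union
render_dots <- function(size, n_objects) {
  canvas <- matrix(0, size, size)
  xs <- runif(n_objects, 1, size)
  ys <- runif(n_objects, 1, size)
  rs <- runif(n_objects, 2, 4)
  for (i in seq_len(n_objects)) {
    r <- rs[i]
    jr <- max(1L, floor(xs[i] - r)):min(size, ceiling(xs[i] + r))
    ir <- max(1L, floor(ys[i] - r)):min(size, ceiling(ys[i] + r))
    dd <- outer((ir - ys[i])^2, (jr - xs[i])^2, `+`)
    canvas[ir, jr] <- pmax(canvas[ir, jr], (dd <= r^2) * 1)
  }
  canvas
}

# shared camera pipeline: blur with the PSF, scale so the mean signal
# photon count equals the budget (photon levels for microscopy data are
# quoted as image averages; sparse structures then get bright peaks),
# add background, draw shot noise
render_to_image <- function(structure_img, spec, sigma = NULL) {
  sigma <- sigma %||% spec$psf_sigma_px
  obj <- gaussian_blur_sigma(structure_img, sigma)
  if (mean(obj) > 0) obj <- obj / mean(obj)
  expected <- spec$background + spec$photon_budget * obj
  p <- if (spec$poisson_noise) {
    matrix(rpois(length(expected), expected), nrow(expected))
  } else expected
  gray_image(pmin(p, 65535), bit_depth = 16L, pixel_size_nm = 32.3)
}

#' Filamentous phantom image
#'
#' Renders smooth random curves (cubic splines through uniformly placed
#' control points, anti-aliased strokes of 1-2 px width) emulating
#' microtubule / F-actin structures, convolves with a Gaussian PSF and
#' adds Poisson shot noise.  Deterministic given the spec's seed.
#'
#' @param spec a [phantom_spec()] with `kind = "filament"`.
#' @return A 16-bit [gray_image()] with 32.3 nm pixel size.
#' @export
filament_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$kind != "filament")
    natimg_error("spec$kind must be 'filament'", "invalid_input")
  withr::with_seed(spec$seed, {
    render_to_image(render_filaments(spec$size_px, spec$n_objects), spec)
  })
}

#' Dot-like phantom image
#'
#' Renders disks of radius 2-4 px at uniform random positions, emulating
#' the "salt and pepper" appearance of clathrin-coated-pit images, then
#' applies the same PSF / noise pipeline as [filament_phantom()].
#'
#' @param spec a [phantom_spec()] with `kind = "dots"`.
#' @return A 16-bit [gray_image()] with 32.3 nm pixel size.
#' @export
dot_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$kind != "dots")
    natimg_error("spec$kind must be 'dots'", "invalid_input")
  withr::with_seed(spec$seed, {
    render_to_image(render_dots(spec$size_px, spec$n_objects), spec)
  })
}

#' Matched low-resolution / high-resolution phantom pair
#'
#' Renders one object set at two PSF widths — the spec's own
#' `psf_sigma_px` for the high-resolution image and the wider
#' `lr_sigma_px` for the diffraction-limited one — with independent
#' noise draws from the same seeded stream, emulating matched wide-field
#' and super-resolution acquisitions of the same structures.
#'
#' @param spec a [phantom_spec()].
#' @param lr_sigma_px low-resolution PSF sigma; must exceed the spec's
#'   `psf_sigma_px`.
#' @return A list with elements `low` and `high` ([gray_image()]s).
#' @export
degraded_pair <- function(spec, lr_sigma_px) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.numeric(lr_sigma_px) || lr_sigma_px <= spec$psf_sigma_px)
    natimg_error("lr_sigma_px must exceed the spec's psf_sigma_px",
                 "invalid_input")
  withr::with_seed(spec$seed, {
    structure_img <- if (spec$kind == "filament")
      render_filaments(spec$size_px, spec$n_objects)
    else render_dots(spec$size_px, spec$n_objects)
    low <- render_to_image(structure_img, spec, sigma = lr_sigma_px)
    high <- render_to_image(structure_img, spec)
    list(low = low, high = high)
  })
}
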