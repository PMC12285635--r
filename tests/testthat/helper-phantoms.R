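# shared fixtures: all test images are generated in code

# small filament phantom, optionally kernel-blurred afterwards
small_filament <- function(seed, size = 128L, pb = 400, psf = 0.8,
                           blur = 0L, noise = TRUE) {
  img <- filament_phantom(phantom_spec("filament", size_px = size,
                                       photon_budget = pb,
                                       psf_sigma_px = psf, seed = seed,
                                       poisson_noise = noise))
  if (blur > 0L) img <- gaussian_blur_renormalize(img, blur)
  img
}

# horizontal ramp I(x, y) = x as a plain matrix
ramp_matrix <- function(n = 8L) matrix(rep(seq_len(n), each = n), n, n)

# exact-model gradient samples: inverse-transform at mid-grid
# probabilities, so the empirical mid-rank CDF reproduces the model
exact_model_values <- function(n, t) {
  natimg:::hl_quantile((seq_len(n) - 0.5) / n, t)
}

expect_natimg_error <- function(expr, class) {
  expect_error(expr, class = paste0("natimg_", class))
}
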