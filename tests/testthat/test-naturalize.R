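test_that("fast cosine transforms match the direct definition", {
  naive_dct <- function(x) {
    n <- length(x)
    vapply(0:(n - 1), function(k)
      sum(x * cos(pi * k * (2 * (0:(n - 1)) + 1) / (2 * n))), numeric(1))
  }
  for (n in c(7L, 8L)) {
    x <- sin(seq_len(n)) + seq_len(n) / 3
    expect_equal(as.vector(natimg:::dct_cols(matrix(x))), naive_dct(x),
                 tolerance = 1e-12)
  }
  X <- matrix(rnorm(30 * 17), 30, 17)
  expect_equal(natimg:::idct2(natimg:::dct2(X)), X, tolerance = 1e-12)
})

test_that("histogram matching fixes exact-model fields and keeps order", {
  # a field already following the target law maps to itself: 12 x 12
  # mid-grid inverse-transform values stay inside the +-255 clamp
  v <- exact_model_values(144, 0.38)
  set.seed(3)
  gx <- matrix(sample(v), 12, 12)
  gy <- matrix(sample(v), 12, 12)
  f <- structure(list(gx = gx, gy = gy, laplacian = gx * 0),
                 class = "gradient_field")
  m <- match_gradient_histogram(f)
  expect_lt(max(abs(m$gx - gx)), 1e-3)
  expect_lt(max(abs(m$gy - gy)), 1e-3)

  # monotonicity: order of any two gradients is preserved
  set.seed(4)
  g <- matrix(rnorm(400, sd = 12), 20, 20)
  f <- structure(list(gx = g, gy = g, laplacian = g * 0),
                 class = "gradient_field")
  m <- match_gradient_histogram(f)
  o <- order(as.vector(g))
  expect_true(all(diff(as.vector(m$gx)[o]) >= 0))

  zero <- structure(list(gx = matrix(0, 5, 5), gy = matrix(0, 5, 5),
                         laplacian = matrix(0, 5, 5)),
                    class = "gradient_field")
  expect_natimg_error(match_gradient_histogram(zero),
                      "degenerate_distribution")
})

test_that("matched fields refit to the target parameter", {
  img <- to_gray8(small_filament(7, size = 128L, blur = 7L))
  m <- match_gradient_histogram(gradient_field(img))
  t1 <- fit_cgd_param(empirical_cumulative(as.vector(m$gx)),
                      empirical_cumulative(as.vector(m$gy)))$t
  expect_lt(abs(t1 - 0.38) / 0.38, 0.10)
})

test_that("reintegration reconstructs consistent fields exactly", {
  img <- small_filament(8, size = 64L)
  f <- gradient_field(img)
  out <- reintegrate(f, img, naturalization_settings(preserve_range = FALSE))
  crop <- img$pixels[2:63, 2:63]
  dev <- out$pixels - crop
  expect_lt(max(abs(dev - mean(dev))), 1e-6)
  # free constant fixed at the reference mean
  expect_lt(abs(mean(out$pixels) - mean(crop)), 1e-9)
})

test_that("reintegration is linear and handles the zero field", {
  zero <- structure(list(gx = matrix(0, 30, 30), gy = matrix(0, 30, 30),
                         laplacian = matrix(0, 30, 30)),
                    class = "gradient_field")
  ref <- gray_image(matrix(runif(32 * 32, 0, 100), 32, 32), 32L)
  out <- reintegrate(zero, ref, naturalization_settings(preserve_range = FALSE))
  expect_lt(diff(range(out$pixels)), 1e-9)
  expect_lt(abs(out$pixels[1, 1] - mean(ref$pixels[2:31, 2:31])), 1e-9)

  ramp <- ramp_matrix(32)
  f <- gradient_field(ramp)
  f2 <- f; f2$gx <- 2 * f$gx; f2$gy <- 2 * f$gy
  out <- reintegrate(f2, gray_image(ramp, 32L),
                     naturalization_settings(preserve_range = FALSE))
  dev <- out$pixels - 2 * ramp[2:31, 2:31]
  expect_lt(max(abs(dev - mean(dev))), 1e-8)

  bad <- zero; bad$gx[1, 1] <- Inf
  expect_natimg_error(reintegrate(bad, ref), "invalid_input")
})

test_that("the DCT Poisson solve matches dense least squares on 16x16", {
  set.seed(5)
  R <- 16L; C <- 16L
  gx <- matrix(rnorm(R * C), R, C)
  gy <- matrix(rnorm(R * C), R, C)
  f <- structure(list(gx = gx, gy = gy, laplacian = gx * 0),
                 class = "gradient_field")
  ref <- gray_image(matrix(0, R, C), 32L)
  fast <- reintegrate(f, ref, naturalization_settings(preserve_range = FALSE))

  # dense design: one row per forward-difference constraint
  idx <- function(i, j) (j - 1L) * R + i
  rows <- list()
  for (j in 1:(C - 1)) for (i in 1:R)
    rows[[length(rows) + 1L]] <- c(idx(i, j + 1), idx(i, j), gx[i, j])
  for (j in 1:C) for (i in 1:(R - 1))
    rows[[length(rows) + 1L]] <- c(idx(i + 1, j), idx(i, j), gy[i, j])
  A <- matrix(0, length(rows), R * C)
  b <- numeric(length(rows))
  for (k in seq_along(rows)) {
    A[k, rows[[k]][1]] <- 1; A[k, rows[[k]][2]] <- -1; b[k] <- rows[[k]][3]
  }
  # pin the free constant with a mean-zero row
  A <- rbind(A, rep(1, R * C)); b <- c(b, 0)
  dense <- matrix(qr.solve(crossprod(A), crossprod(A, b)), R, C)
  dev <- fast$pixels - mean(fast$pixels) - dense
  expect_lt(max(abs(dev)) / max(abs(dense)), 1e-8)
})

test_that("naturalization moves the naturalness factor toward one", {
  cases <- list(small_filament(9, pb = 20),
                small_filament(10),
                small_filament(11, blur = 5L),
                small_filament(12, blur = 9L))
  nf_in <- vapply(cases, function(i) naturalness_factor(i)$nf, numeric(1))
  nf_out <- vapply(cases, function(i) naturalness_factor(naturalize(i))$nf,
                   numeric(1))
  expect_lt(median(abs(nf_out - 1)), median(abs(nf_in - 1)))
  expect_true(all(abs(nf_out - 1) <= abs(nf_in - 1) + 0.05))
  # the strongly blurred image lands close to the target
  expect_lt(abs(nf_out[4] - 1), 0.35)

  expect_natimg_error(naturalize(gray_image(matrix(4, 64, 64), 16L)),
                      "degenerate_distribution")
})

test_that("naturalization is approximately idempotent", {
  for (img in list(small_filament(13), small_filament(14, blur = 7L))) {
    n1 <- naturalize(img)
    n2 <- naturalize(n1)
    expect_lt(abs(naturalness_factor(n2)$nf - naturalness_factor(n1)$nf),
              0.05)
  }
})

test_that("naturalized output keeps bit depth and intensity range", {
  img <- small_filament(15, size = 96L)
  out <- naturalize(img)
  expect_equal(out$bit_depth, 16L)
  expect_equal(dim(out$pixels), dim(img$pixels) - 2L)
  expect_gte(min(out$pixels), min(img$pixels))
  expect_lte(max(out$pixels), max(img$pixels))
})
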