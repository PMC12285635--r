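fake_reports <- function(df) {
  lapply(seq_len(nrow(df)), function(i)
    metric_report(mae = df$mae[i], psnr = df$psnr[i],
                  ms_ssim = df$ms_ssim[i], contrast = df$contrast[i],
                  resolution_nm = df$resolution_nm[i], nf = df$nf[i]))
}

random_reports <- function(n, seed) {
  set.seed(seed)
  fake_reports(data.frame(
    mae = runif(n), psnr = rnorm(n, 20), ms_ssim = runif(n),
    contrast = runif(n, 10, 30), resolution_nm = runif(n, 80, 150),
    nf = rnorm(n, 1, 0.2)))
}

test_that("batch evaluation scores identical pairs perfectly", {
  img <- small_filament(1, size = 192L)
  pairs <- replicate(3, list(generated = img, reference = img),
                     simplify = FALSE)
  reports <- batch_evaluate(pairs)
  for (r in reports) {
    expect_equal(r$mae, 0)
    expect_equal(r$ms_ssim, 1, tolerance = 1e-6)
    expect_true("psnr" %in% r$flags)   # MSE = 0 has no finite PSNR
  }
  expect_natimg_error(batch_evaluate(list()), "invalid_input")
})

test_that("a degenerate image is flagged without breaking the corpus", {
  good <- small_filament(2, size = 192L)
  flat <- gray_image(matrix(40, 192, 192), 16L, pixel_size_nm = 32.3)
  reports <- batch_evaluate(list(
    list(generated = flat, reference = good),
    list(generated = good, reference = good)))
  expect_true("nf" %in% reports[[1]]$flags)
  expect_true(is.na(reports[[1]]$nf))
  expect_false("nf" %in% reports[[2]]$flags)
  expect_false(is.na(reports[[2]]$nf))
})

test_that("correlation cells match the t-distribution oracle", {
  reports <- random_reports(100, seed = 8)
  cells <- metric_correlations(reports)
  expect_equal(nrow(cells), 15L)            # 6 metrics, unordered pairs
  expect_true(all(cells$n == 100L))
  expect_equal(cells$r_squared, cells$r^2, tolerance = 1e-12)
  # p-values agree with cor.test (two-sided t, n - 2 dof)
  df <- natimg:::reports_to_frame(reports)
  for (k in c(1L, 7L, 15L)) {
    ct <- cor.test(df[[cells$metric_a[k]]], df[[cells$metric_b[k]]])
    expect_equal(cells$p_value[k], ct$p.value, tolerance = 1e-12)
    expect_equal(cells$r[k], unname(ct$estimate), tolerance = 1e-12)
  }
})

test_that("perfect and degenerate correlations are handled", {
  df <- data.frame(mae = runif(20), psnr = rnorm(20), ms_ssim = runif(20),
                   contrast = runif(20), resolution_nm = runif(20),
                   nf = rnorm(20))
  df$psnr <- df$mae * 3 + 1                # duplicated information
  cells <- metric_correlations(fake_reports(df))
  dup <- cells[cells$metric_a == "mae" & cells$metric_b == "psnr", ]
  expect_equal(dup$r, 1, tolerance = 1e-12)
  expect_lt(dup$p_value, 1e-12)

  df$contrast <- 5                         # zero variance
  cells <- metric_correlations(fake_reports(df))
  con <- cells[cells$metric_a == "contrast" | cells$metric_b == "contrast", ]
  expect_true(all(con$note == "degenerate-metric"))
  expect_true(all(is.na(con$r)))

  expect_natimg_error(metric_correlations(random_reports(3, 1)),
                      "invalid_input")
})

test_that("t-test p-values agree with a permutation test", {
  set.seed(10)
  n <- 30L
  x <- rnorm(n)
  y <- 0.5 * x + rnorm(n, sd = 1)
  r_obs <- cor(x, y)
  p_t <- natimg:::pearson_p_value(r_obs, n)
  perm <- replicate(1e4, abs(cor(x, sample(y))))
  p_perm <- mean(perm >= abs(r_obs))
  expect_lt(abs(p_t - p_perm), 0.02)
})

test_that("independent metrics stay uncorrelated", {
  ok <- vapply(1:20, function(s) {
    reports <- random_reports(1000, seed = 100 + s)
    cells <- metric_correlations(reports)
    all(abs(cells$r) < 0.1) && all(cells$p_value > 0.001)
  }, logical(1))
  expect_gte(sum(ok), 19L)
})

test_that("the correlation matrix is symmetric with unit diagonal", {
  cells <- metric_correlations(random_reports(50, seed = 12))
  M <- correlation_matrix(cells)
  expect_equal(M, t(M))
  expect_true(all(diag(M) == 1))
  expect_true(all(cells$p_value >= 0 & cells$p_value <= 1))
})

test_that("reports round-trip losslessly through disk", {
  reports <- random_reports(25, seed = 13)
  cells <- metric_correlations(reports)
  dir <- file.path(tempdir(), "natimg_report")
  write_report(cells, reports, dir)
  back <- read_report(dir)
  expect_equal(nrow(back$cells), 15L)
  expect_equal(back$cells$r, cells$r, tolerance = 1e-12)
  expect_equal(back$cells$p_value, cells$p_value, tolerance = 1e-12)
  expect_equal(back$reports$mae,
               vapply(reports, `[[`, numeric(1), "mae"), tolerance = 1e-12)

  # reports-only output when there are no cells
  dir2 <- file.path(tempdir(), "natimg_report2")
  write_report(NULL, reports, dir2)
  back2 <- read_report(dir2)
  expect_null(back2$cells)
  expect_equal(nrow(back2$reports), 25L)
})
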