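# Batch scoring of image corpora and pairwise metric-correlation
# analysis with two-sided t-tests (n - 2 degrees of freedom).

metric_names <- c("ms_ssim", "mae", "psnr", "contrast", "resolution_nm",
                  "one_minus_nf")

#' Construct a metric report
#'
#' One row of a corpus evaluation: named metric values for a (generated,
#' reference) pair, with `flags` listing metrics that could not be
#' computed.
#'
#' @param mae,psnr,ms_ssim,contrast,resolution_nm,nf metric values
#'   (NA when unavailable).
#' @param flags character vector of failed metric names.
#' @return A `metric_report`.
#' @export
metric_report <- function(mae = NA_real_, psnr = NA_real_,
                          ms_ssim = NA_real_, contrast = NA_real_,
                          resolution_nm = NA_real_, nf = NA_real_,
                          flags = character()) {
  structure(list(mae = mae, psnr = psnr, ms_ssim = ms_ssim,
                 contrast = contrast, resolution_nm = resolution_nm,
                 nf = nf, flags = flags),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<metric_report MAE %.4g | PSNR %.4g dB | MS-SSIM %.4g | ",
    "contrast %.4g | resolution %.4g nm | N_f %.4g%s>\n"),
    x$mae, x$psnr, x$ms_ssim, x$contrast, x$resolution_nm, x$nf,
    if (length(x$flags)) paste0(" | flags: ",
                                paste(x$flags, collapse = ",")) else ""))
  invisible(x)
}

#' Evaluate all metrics over a corpus of image pairs
#'
#' For every (generated, reference) pair: MAE and PSNR on the two images
#' min-max normalized to `[0, 1]` independently (PSNR with unit peak),
#' MS-SSIM, plus the reference-free metrics of the generated image (RMS
#' contrast on its raw intensities, decorrelation resolution, and the
#' naturalness factor).  A metric failure (e.g. a constant image with a
#' degenerate gradient distribution) is recorded in that report's
#' `flags` and does not abort the remaining corpus.
#'
#' @param pairs list of `list(generated = , reference = )` image pairs.
#' @param prior a [naturalness_prior()].
#' @param theta naturalness weight in `[0, 1]`.
#' @return A list of [metric_report()] objects.
#' @export
batch_evaluate <- function(pairs, prior = naturalness_prior(),
                           theta = 0.5) {
  if (!is.list(pairs) || length(pairs) == 0L)
    natimg_error("pairs must be a non-empty list", "invalid_input")
  lapply(pairs, function(pr) {
    gen <- as_gray_image(pr$generated)
    ref <- as_gray_image(pr$reference)
    flags <- character()
    grab <- function(name, expr) {
      tryCatch(expr, error = function(e) {
        flags <<- c(flags, name)
        NA_real_
      })
    }
    gn <- minmax01(gen$pixels); rn <- minmax01(ref$pixels)
    v_mae <- grab("mae", mae(gn, rn))
    v_psnr <- grab("psnr", psnr(gn, rn, max_intensity = 1))
    v_ssim <- grab("ms_ssim", ms_ssim(gen, ref))
    v_con <- grab("contrast", rms_contrast(gen))
    v_res <- grab("resolution_nm", decorrelation_curve(gen)$resolution_nm)
    v_nf <- grab("nf", naturalness_factor(gen, prior, theta)$nf)
    metric_report(mae = v_mae, psnr = v_psnr, ms_ssim = v_ssim,
                  contrast = v_con, resolution_nm = v_res, nf = v_nf,
                  flags = flags)
  })
}

reports_to_frame <- function(reports) {
  stopifnot(is.list(reports), length(reports) > 0L)
  data.frame(
    ms_ssim = vapply(reports, `[[`, numeric(1), "ms_ssim"),
    mae = vapply(reports, `[[`, numeric(1), "mae"),
    psnr = vapply(reports, `[[`, numeric(1), "psnr"),
    contrast = vapply(reports, `[[`, numeric(1), "contrast"),
    resolution_nm = vapply(reports, `[[`, numeric(1), "resolution_nm"),
    one_minus_nf = 1 - vapply(reports, `[[`, numeric(1), "nf"))
}

# two-sided p-value of Pearson r from Student's t with n - 2 dof
pearson_p_value <- function(r, n) {
  if (is.na(r) || n < 3L) return(NA_real_)
  if (abs(r) >= 1) return(0)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
}

#' Pairwise Pearson correlations between metrics across a corpus
#'
#' Computes Pearson r for every unordered pair of the six metric columns
#' (MS-SSIM, MAE, PSNR, Contrast, Resolution, 1 - N_f; the naturalness
#' factor enters as its deviation from the target 1 because it is not
#' monotone in quality).  Each cell uses pairwise-complete observations;
#' `R^2 = r^2`; the p-value comes from a two-sided Student's t-test with
#' `n - 2` degrees of freedom.  A metric with zero variance yields NA
#' cells annotated "degenerate-metric" rather than aborting the call.
#'
#' @param reports list of [metric_report()]s, at least 4 complete rows.
#' @return A data.frame of correlation cells: `metric_a`, `metric_b`,
#'   `r`, `r_squared`, `p_value`, `n`, `note`.
#' @export
metric_correlations <- function(reports) {
  df <- reports_to_frame(reports)
  if (sum(stats::complete.cases(df)) < 4L)
    natimg_error("need at least 4 complete reports for correlations",
                 "invalid_input")
  cols <- metric_names
  combs <- utils::combn(cols, 2L)
  cells <- lapply(seq_len(ncol(combs)), function(k) {
    a <- combs[1L, k]; b <- combs[2L, k]
    ok <- stats::complete.cases(df[, c(a, b)])
    x <- df[[a]][ok]; y <- df[[b]][ok]
    n <- length(x)
    if (n < 3L || sd(x) == 0 || sd(y) == 0) {
      return(data.frame(metric_a = a, metric_b = b, r = NA_real_,
                        r_squared = NA_real_, p_value = NA_real_,
                        n = n, note = "degenerate-metric"))
    }
    r <- cor(x, y)
    data.frame(metric_a = a, metric_b = b, r = r, r_squared = r^2,
               p_value = pearson_p_value(r, n), n = n, note = "")
  })
  do.call(rbind, cells)
}

#' Assemble correlation cells into a symmetric matrix
#'
#' @param cells output of [metric_correlations()].
#' @return A symmetric numeric matrix with unit diagonal.
#' @export
correlation_matrix <- function(cells) {
  nm <- unique(c(cells$metric_a, cells$metric_b))
  M <- diag(1, length(nm))
  dimnames(M) <- list(nm, nm)
  for (i in seq_len(nrow(cells))) {
    M[cells$metric_a[i], cells$metric_b[i]] <- cells$r[i]
    M[cells$metric_b[i], cells$metric_a[i]] <- cells$r[i]
  }
  M
}

fmt_num <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))

#' Write corpus reports and correlation cells to CSV and JSON
#'
#' Writes `reports.csv` (one row per image pair), `correlations.csv`
#' (long form, one row per metric pair) and `correlations.json` (nested)
#' under `path`.  Values round-trip losslessly through [read_report()].
#'
#' @param cells output of [metric_correlations()] (may be NULL).
#' @param reports list of [metric_report()]s.
#' @param path output directory (created if missing).
#' @return Invisibly, `path`.
#' @export
write_report <- function(cells, reports, path) {
  ok <- tryCatch({
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    file.access(path, 2L) == 0L
  }, error = function(e) FALSE)
  if (!ok) natimg_error(paste("cannot write to", path), "io_error")
  df <- reports_to_frame(reports)
  df$flags <- vapply(reports, function(r) paste(r$flags, collapse = ";"),
                     character(1))
  out <- df
  for (nm in metric_names) out[[nm]] <- fmt_num(df[[nm]])
  write.csv(out, file.path(path, "reports.csv"), row.names = FALSE)
  if (!is.null(cells) && nrow(cells) > 0L) {
    cc <- cells
    for (nm in c("r", "r_squared", "p_value")) cc[[nm]] <- fmt_num(cells[[nm]])
    write.csv(cc, file.path(path, "correlations.csv"), row.names = FALSE)
    jsonlite::write_json(cells, file.path(path, "correlations.json"),
                         dataframe = "rows", na = "null", digits = NA,
                         auto_unbox = TRUE)
  }
  invisible(path)
}

#' Read back a report directory written by [write_report()]
#'
#' @param path directory containing `reports.csv` and optionally
#'   `correlations.csv`.
#' @return A list with `reports` (data.frame) and `cells` (data.frame or
#'   NULL).
#' @export
read_report <- function(path) {
  rp <- file.path(path, "reports.csv")
  if (!file.exists(rp)) natimg_error(paste("no reports.csv in", path),
                                     "io_error")
  reports <- read.csv(rp, stringsAsFactors = FALSE)
  for (nm in metric_names) reports[[nm]] <- as.numeric(reports[[nm]])
  cp <- file.path(path, "correlations.csv")
  cells <- if (file.exists(cp)) {
    cc <- read.csv(cp, stringsAsFactors = FALSE)
    for (nm in c("r", "r_squared", "p_value")) cc[[nm]] <- as.numeric(cc[[nm]])
    cc
  } else NULL
  list(reports = reports, cells = cells)
}
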