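# Image-quality evaluation: PSNR and SSIM per pair, mean/SD aggregates and
# Tukey boxplot statistics, including the no-model "noisy baseline" row
# (metrics of the raw noisy input against the reference).

#' Peak signal-to-noise ratio
#'
#' `10 * log10(data_range^2 / MSE)` over all pixels, in dB. Identical
#' images (zero MSE) return the 100 dB sentinel, and all values are capped
#' at 100 dB so aggregates stay finite.
#'
#' @param reference,test Same-shape numeric matrices.
#' @param data_range Intensity range of the data (1.0 on the normalized
#'   scale used throughout this package; absolute dB values depend on it).
#' @export
psnr <- function(reference, test, data_range = 1.0) {
  if (!all(dim(reference) == dim(test))) stop("shape mismatch")
  stopifnot(data_range > 0)
  mse <- mean((reference - test)^2)
  if (mse == 0) return(100)
  min(10 * log10(data_range^2 / mse), 100)
}

gauss_band <- function(n, win = 11L, sigma = 1.5) {
  half <- (win - 1L) %/% 2L
  w <- stats::dnorm(-half:half, sd = sigma)
  w <- w / sum(w)
  n_out <- n - win + 1L
  G <- matrix(0, n_out, n)
  for (i in seq_len(n_out)) G[i, i:(i + win - 1L)] <- w
  G
}

#' Structural similarity index
#'
#' Windowed SSIM with an 11 x 11 Gaussian window (sigma 1.5), stability
#' constants K1 = 0.01 and K2 = 0.03, computed on fully interior windows
#' and averaged. Symmetric in its arguments; exactly 1 iff the images are
#' identical.
#'
#' @param reference,test Same-shape numeric matrices, at least 11 x 11.
#' @param data_range Intensity range L entering `C1 = (K1 L)^2`,
#'   `C2 = (K2 L)^2`.
#' @export
ssim <- function(reference, test, data_range = 1.0) {
  if (!all(dim(reference) == dim(test))) stop("shape mismatch")
  win <- 11L
  if (nrow(reference) < win || ncol(reference) < win) {
    stop("image smaller than the ", win, "x", win, " SSIM window")
  }
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  GR <- gauss_band(nrow(reference), win)
  GC <- t(gauss_band(ncol(reference), win))
  f <- function(img) GR %*% img %*% GC
  mu1 <- f(reference); mu2 <- f(test)
  s11 <- f(reference * reference) - mu1 * mu1
  s22 <- f(test * test) - mu2 * mu2
  s12 <- f(reference * test) - mu1 * mu2
  num <- (2 * mu1 * mu2 + C1) * (2 * s12 + C2)
  den <- (mu1 * mu1 + mu2 * mu2 + C1) * (s11 + s22 + C2)
  mean(num / den)
}

#' Tukey boxplot statistics
#'
#' Median and linear-interpolation (type 7) quartiles; whiskers reach the
#' furthest datum within 1.5 IQR of its quartile; everything beyond is an
#' outlier. The mean is included because the published boxplots mark it.
#'
#' @param values Non-empty numeric vector.
#' @return List with `median`, `q1`, `q3`, `whisker_lo`, `whisker_hi`,
#'   `outliers`, `mean`.
#' @export
boxplot_stats <- function(values) {
  if (length(values) == 0L) stop("empty input")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lo_f <- q[1] - 1.5 * iqr
  hi_f <- q[3] + 1.5 * iqr
  inside <- values[values >= lo_f & values <= hi_f]
  list(median = q[2], q1 = q[1], q3 = q[3],
       whisker_lo = min(inside), whisker_hi = max(inside),
       outliers = sort(values[values < lo_f | values > hi_f]),
       mean = mean(values))
}

#' Evaluate a model (or the noisy baseline) on a test manifest
#'
#' With `model = NULL`, computes the metrics of the raw noisy inputs
#' against their references — the baseline row of the results table.
#' Otherwise each input is denoised with [denoise_image()] first. Per-image
#' values are retained for boxplots; the SD uses the sample (n-1)
#' convention.
#'
#' @param model A `sim_model` or `NULL` for the baseline.
#' @param manifest Non-empty test `dataset_manifest`.
#' @return A `metric_report`: list with `per_image` (data frame),
#'   `mean_psnr`, `sd_psnr`, `mean_ssim`, `sd_ssim`, `n`, and `boxplot`
#'   (per-metric Tukey statistics).
#' @export
evaluate_model <- function(model, manifest) {
  if (nrow(manifest) == 0L) stop("empty test manifest")
  n <- nrow(manifest)
  ps <- numeric(n); ss <- numeric(n)
  for (i in seq_len(n)) {
    pr <- load_pair(manifest[i, ])
    test <- if (is.null(model)) pr$input else denoise_image(model, pr$input)
    ps[i] <- psnr(pr$reference, test)
    ss[i] <- ssim(pr$reference, test)
  }
  per_image <- data.frame(fov_id = manifest$fov_id,
                          input_timestamp = manifest$input_timestamp,
                          psnr = ps, ssim = ss)
  structure(list(per_image = per_image, n = n,
                 mean_psnr = mean(ps), sd_psnr = stats::sd(ps),
                 mean_ssim = mean(ss), sd_ssim = stats::sd(ss),
                 boxplot = list(psnr = boxplot_stats(ps),
                                ssim = boxplot_stats(ss))),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("metric report over %d image pairs\n", x$n))
  cat(sprintf("  PSNR: %.2f dB (SD %.2f)\n", x$mean_psnr, x$sd_psnr))
  cat(sprintf("  SSIM: %.4f (SD %.4f)\n", x$mean_ssim, x$sd_ssim))
  invisible(x)
}

#' Write a metric report to disk
#'
#' Per-image values as CSV, aggregates (and boxplot statistics) as JSON.
#'
#' @param report A `metric_report`.
#' @param dir Output directory.
#' @export
write_metric_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$per_image, file.path(dir, "per_image.csv"),
                   row.names = FALSE)
  agg <- list(n = report$n, mean_psnr = report$mean_psnr,
              sd_psnr = report$sd_psnr, mean_ssim = report$mean_ssim,
              sd_ssim = report$sd_ssim, boxplot = report$boxplot)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(agg, file.path(dir, "aggregates.json"),
                         auto_unbox = TRUE, digits = NA)
  } else {
    dput(agg, file.path(dir, "aggregates.R"))
  }
  invisible(dir)
}
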