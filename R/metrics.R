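#' Root-mean-square error between paired grids
#'
#' `sqrt(mean((ref - test)^2))`, in the units of the input (counts for
#' projection data).
#'
#' @param ref,test Numeric arrays or vectors of identical shape.
#' @return A single nonnegative number.
#' @export
rmse <- function(ref, test) {
  check_same_shape(ref, test)
  sqrt(mean((as.numeric(ref) - as.numeric(test))^2))
}

check_same_shape <- function(ref, test) {
  if (!identical(dim(ref) %||% length(ref), dim(test) %||% length(test))) {
    abort_param("`ref` and `test` must have identical shape")
  }
  if (length(ref) < 1L) abort_param("inputs must be non-empty")
  invisible(TRUE)
}

#' Peak signal-to-noise ratio
#'
#' The default variant is the standard `20 * log10(Peak / RMSE)`. The
#' `"peak_over_mse"` variant, `20 * log10(Peak / MSE)`, is also selectable;
#' it divides by the *squared* error and is retained because some reports
#' print the formula that way. `Peak` defaults to the maximum of the test
#' (low-dose or predicted) data; `"reference"` uses the maximum of `ref`.
#'
#' @param ref,test Numeric arrays of identical shape; `ref` is the
#'   standard-dose reference.
#' @param peak Which image supplies the peak: `"test"` (default) or
#'   `"reference"`.
#' @param variant `"peak_over_rmse"` (default) or `"peak_over_mse"`.
#' @return PSNR in dB; `Inf` (with a warning) for identical inputs.
#' @examples
#' psnr(c(10, 10, 10, 10), c(8, 12, 8, 12)) # 20*log10(12/2)
#' @export
psnr <- function(ref, test, peak = c("test", "reference"),
                 variant = c("peak_over_rmse", "peak_over_mse")) {
  check_same_shape(ref, test)
  peak <- match.arg(peak)
  variant <- match.arg(variant)
  pk <- if (peak == "test") max(test) else max(ref)
  if (pk <= 0) abort_param("peak value is not positive; PSNR undefined")
  mse <- mean((as.numeric(ref) - as.numeric(test))^2)
  if (mse == 0) {
    warning("identical inputs: PSNR is infinite", call. = FALSE)
    return(Inf)
  }
  denom <- if (variant == "peak_over_rmse") sqrt(mse) else mse
  20 * log10(pk / denom)
}

#' Global structural similarity index
#'
#' Single-window SSIM computed from the global first and second moments of
#' the two images:
#' `(2*mu_y*mu_t + C1) * (2*cov + C2) / ((mu_y^2 + mu_t^2 + C1) * (var_y + var_t + C2))`.
#' The stabilising constants are absolute (`C1 = 0.01`, `C2 = 0.02` by
#' default), not scaled by a dynamic range; no sliding window is used.
#'
#' @param ref,test Numeric arrays of identical shape with at least 2 elements.
#' @param C1,C2 Stabilising constants.
#' @return SSIM in `[-1, 1]` for nonnegative images; exactly 1 for identical
#'   inputs.
#' @export
ssim_global <- function(ref, test, C1 = 0.01, C2 = 0.02) {
  check_same_shape(ref, test)
  y <- as.numeric(ref); t <- as.numeric(test)
  if (length(y) < 2L) abort_param("SSIM needs at least 2 elements")
  mu_y <- mean(y); mu_t <- mean(t)
  n <- length(y)
  # population (1/n) moments: the formula's variance/covariance symbols
  var_y <- sum((y - mu_y)^2) / n
  var_t <- sum((t - mu_t)^2) / n
  cov_yt <- sum((y - mu_y) * (t - mu_t)) / n
  ((2 * mu_y * mu_t + C1) * (2 * cov_yt + C2)) /
    ((mu_y^2 + mu_t^2 + C1) * (var_y + var_t + C2))
}

#' Pearson product-moment correlation
#'
#' Explicit sum-form evaluation of the correlation coefficient between two
#' paired grids (e.g. reconstructed volumes, or derived per-patient indices).
#'
#' @param ref,test Numeric arrays of identical shape, each with nonzero
#'   variance.
#' @param mask Optional logical array restricting the correlation to a
#'   region (e.g. a myocardial mask); default all voxels.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson <- function(ref, test, mask = NULL) {
  check_same_shape(ref, test)
  y <- as.numeric(ref); t <- as.numeric(test)
  if (!is.null(mask)) {
    y <- y[as.logical(mask)]
    t <- t[as.logical(mask)]
  }
  if (length(y) < 2L) abort_param("correlation needs at least 2 elements")
  dy <- y - mean(y); dt <- t - mean(t)
  sy <- sqrt(sum(dy^2)); st <- sqrt(sum(dt^2))
  if (sy == 0 || st == 0) {
    abort_param("correlation undefined: an input has zero variance")
  }
  sum(dy * dt) / (sy * st)
}

#' Paired image-quality metrics as a tibble
#'
#' Convenience wrapper computing PSNR, RMSE, global SSIM and Pearson
#' correlation for one (reference, test) pair.
#'
#' @inheritParams psnr
#' @param label Optional label column (e.g. `"half_dose"`).
#' @return A one-row tibble with columns `label`, `psnr_db`, `rmse`, `ssim`,
#'   `pearson_rho`.
#' @export
metrics_report <- function(ref, test, label = NA_character_,
                           peak = "test", variant = "peak_over_rmse") {
  tibble::tibble(
    label = label,
    psnr_db = psnr(ref, test, peak = peak, variant = variant),
    rmse = rmse(ref, test),
    ssim = ssim_global(ref, test),
    pearson_rho = pearson(ref, test)
  )
}

#' Bland-Altman agreement analysis
#'
#' Agreement between paired measurements: the bias is the mean of
#' `test - ref`, the limits of agreement are `bias +/- 1.96 * sd` of the
#' differences (sample sd, `n - 1` denominator), and a two-sided paired
#' t-test is reported alongside the Pearson correlation of the pairs.
#' With `limits = "ci_of_bias"` the interval is instead the 95% confidence
#' interval of the bias itself (`bias +/- 1.96 * sd / sqrt(n)`), an
#' alternative convention seen on some agreement plots.
#'
#' @param ref_values,test_values Paired numeric vectors of equal length >= 2.
#' @param limits `"loa"` (default, limits of agreement) or `"ci_of_bias"`.
#' @return An object of class `bland_altman`; see [glance.bland_altman()]
#'   and [autoplot.bland_altman()].
#' @export
bland_altman <- function(ref_values, test_values, limits = c("loa", "ci_of_bias")) {
  limits <- match.arg(limits)
  if (length(ref_values) != length(test_values)) {
    abort_param("paired vectors must have equal length")
  }
  n <- length(ref_values)
  if (n < 2L) abort_param("need at least 2 pairs")
  d <- test_values - ref_values
  bias <- mean(d)
  sd_d <- stats::sd(d)
  half <- if (limits == "loa") 1.96 * sd_d else 1.96 * sd_d / sqrt(n)
  tt <- if (sd_d > 0) stats::t.test(test_values, ref_values, paired = TRUE)
  rho <- if (stats::sd(ref_values) > 0 && stats::sd(test_values) > 0) {
    pearson(ref_values, test_values)
  } else {
    NA_real_
  }
  structure(
    list(bias = bias, loa_low = bias - half, loa_high = bias + half,
         sd_diff = sd_d, pearson_rho = rho,
         t_stat = if (!is.null(tt)) unname(tt$statistic) else NA_real_,
         p_value = if (!is.null(tt)) tt$p.value else NA_real_,
         n = n, limits = limits,
         ref = ref_values, test = test_values, differences = d),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "<bland_altman> n = %d, bias = %.4g, limits [%.4g, %.4g], rho = %.4g, p = %.3g\n",
    x$n, x$bias, x$loa_low, x$loa_high, x$pearson_rho, x$p_value))
  invisible(x)
}

#' Tidy the per-pair values of a Bland-Altman analysis
#'
#' @param x A [bland_altman()] object.
#' @param ... Unused.
#' @return A tibble with one row per pair: `mean` of the pair and
#'   `difference` (test - ref).
#' @method tidy bland_altman
#' @export
tidy.bland_altman <- function(x, ...) {
  tibble::tibble(mean = (x$ref + x$test) / 2, difference = x$differences)
}

#' One-row summary of a Bland-Altman analysis
#'
#' @param x A [bland_altman()] object.
#' @param ... Unused.
#' @return A one-row tibble: `bias`, `loa_low`, `loa_high`, `sd_diff`,
#'   `pearson_rho`, `t_stat`, `p_value`, `n`.
#' @method glance bland_altman
#' @export
glance.bland_altman <- function(x, ...) {
  tibble::tibble(bias = x$bias, loa_low = x$loa_low, loa_high = x$loa_high,
                 sd_diff = x$sd_diff, pearson_rho = x$pearson_rho,
                 t_stat = x$t_stat, p_value = x$p_value, n = x$n)
}

#' Bland-Altman plot
#'
#' @param object A [bland_altman()] object.
#' @param ... Unused.
#' @return A ggplot object: pair means vs differences with the bias and
#'   agreement-limit lines dashed.
#' @method autoplot bland_altman
#' @export
autoplot.bland_altman <- function(object, ...) {
  df <- tidy.bland_altman(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$difference)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$bias, colour = "blue") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "mean of pair", y = "difference (test - ref)") +
    ggplot2::theme_minimal()
}

#' Percent change between two summary values
#'
#' `100 * (new - baseline) / baseline` for quantities reported as increases
#' (PSNR, SSIM), and `100 * (baseline - new) / baseline` for quantities
#' reported as decreases (RMSE), matching how improvement percentages are
#' quoted in the imaging literature.
#'
#' @param baseline,new Summary values (vectorised); `baseline` must be
#'   nonzero.
#' @param direction `"increase"` (default) or `"decrease"`.
#' @return Percent change (a plain number, e.g. `12.4` for 12.4%).
#' @export
percent_change <- function(baseline, new, direction = c("increase", "decrease")) {
  direction <- match.arg(direction)
  if (any(baseline == 0)) abort_param("`baseline` must be nonzero")
  if (direction == "increase") 100 * (new - baseline) / baseline
  else 100 * (baseline - new) / baseline
}

#' Reference cohort image-quality means
#'
#' Published mean projection-space image-quality metrics of a 345-patient
#' clinical low-dose SPECT-MPI cohort (35-patient test set), for the
#' low-dose and network-predicted arms at half, quarter and one-eighth dose.
#' Shipped as package data so the percent-change reporting can be exercised
#' against established cohort-level values.
#'
#' @return A tibble with columns `metric` (psnr, ssim, rmse), `dose`
#'   (`"half"`, `"quarter"`, `"eighth"`), `low_dose` and `predicted` means.
#' @export
reference_cohort_metrics <- function() {
  path <- system.file("extdata", "reference_cohort_metrics.csv",
                      package = "spectdenoise", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Percent improvements from cohort metric means
#'
#' Applies [percent_change()] to a table of per-arm metric means (PSNR and
#' SSIM as increases, RMSE as a decrease from the low-dose baseline to the
#' predicted arm).
#'
#' @param means A tibble like [reference_cohort_metrics()]: columns `metric`,
#'   `dose`, `low_dose`, `predicted`.
#' @return The input with a `percent_change` column appended.
#' @export
cohort_percent_changes <- function(means = reference_cohort_metrics()) {
  means <- tibble::as_tibble(means)
  means$direction <- ifelse(means$metric == "rmse", "decrease", "increase")
  means$percent_change <- purrr::pmap_dbl(
    list(means$low_dose, means$predicted, means$direction),
    function(b, n, d) percent_change(b, n, direction = d))
  means
}
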