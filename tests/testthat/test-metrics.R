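test_that("rmse matches hand-computed values and scales homogeneously", {
  expect_identical(rmse(1:5, 1:5), 0)
  expect_equal(rmse(c(1, 2, 3, 4), c(1, 2, 3, 8)), 2.0, tolerance = 1e-12)
  x <- runif(20); y <- runif(20)
  expect_equal(rmse(3 * x, 3 * y), 3 * rmse(x, y), tolerance = 1e-12)
  expect_error(rmse(1:4, 1:5), "identical shape")
})

test_that("psnr reproduces the worked example and its conventions", {
  # Peak = 12 (test max), MSE = 4 -> 20 log10(12 / 2)
  expect_equal(psnr(c(10, 10, 10, 10), c(8, 12, 8, 12)),
               20 * log10(12 / 2), tolerance = 1e-9)
  expect_equal(psnr(c(10, 10, 10, 10), c(8, 12, 8, 12),
                    variant = "peak_over_mse"),
               20 * log10(12 / 4), tolerance = 1e-9)
  expect_equal(psnr(c(10, 10, 10, 10), c(8, 12, 8, 12), peak = "reference"),
               20 * log10(10 / 2), tolerance = 1e-9)
  # scale invariance of the default variant
  x <- runif(50) * 10; y <- x + rnorm(50)
  expect_equal(psnr(2 * x, 2 * y), psnr(x, y), tolerance = 1e-9)
  expect_warning(p <- psnr(c(1, 2), c(1, 2)), "infinite")
  expect_identical(p, Inf)
})

test_that("global SSIM follows the stabilised moment formula", {
  x <- runif(64)
  expect_equal(ssim_global(x, x), 1, tolerance = 1e-12)
  expect_equal(ssim_global(rep(0, 10), rep(0, 10)), 1, tolerance = 1e-12)
  # hand evaluation for ref (0,1), test (1,0)
  hand <- ((2 * 0.25 + 0.01) * (2 * -0.25 + 0.02)) /
    ((0.25 + 0.25 + 0.01) * (0.25 + 0.25 + 0.02))
  expect_equal(ssim_global(c(0, 1), c(1, 0)), hand, tolerance = 1e-12)
})

test_that("pearson matches the explicit sum formula and stats::cor", {
  x <- 1:5
  expect_equal(pearson(x, 2 * x + 1), 1, tolerance = 1e-12)
  expect_equal(pearson(x, -x), -1, tolerance = 1e-12)
  y <- c(2, 1, 4, 3, 5)
  expect_equal(pearson(x, y), 0.8, tolerance = 1e-12)
  expect_equal(pearson(x, y), stats::cor(x, y), tolerance = 1e-12)
  expect_error(pearson(rep(1, 5), 1:5), "zero variance")
  # mask restricts the computation
  m <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  expect_equal(pearson(x, y, mask = m), stats::cor(x[m], y[m]),
               tolerance = 1e-12)
})

test_that("bland_altman reports bias, limits and paired test correctly", {
  expect_s3_class(bland_altman(1:5, 1:5 + 3), "bland_altman")
  shifted <- bland_altman(1:5, 1:5 + 3)
  expect_equal(shifted$bias, 3)
  expect_equal(shifted$loa_low, 3)
  expect_equal(shifted$loa_high, 3)

  ref <- c(0, 0, 0, 0)
  test <- c(1, -1, 2, -2)
  ba <- bland_altman(ref, test)
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd_diff, sqrt(10 / 3), tolerance = 1e-12)
  expect_equal(ba$loa_high, 1.96 * sqrt(10 / 3), tolerance = 1e-12)
  tt <- t.test(test, ref, paired = TRUE)
  expect_equal(ba$t_stat, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(ba$p_value, tt$p.value, tolerance = 1e-12)
  expect_true(ba$loa_low <= ba$bias && ba$bias <= ba$loa_high)

  g <- glance(ba)
  expect_s3_class(g, "tbl_df")
  expect_identical(g$n, 4L)
  expect_error(bland_altman(1:3, 1:4), "equal length")
})

test_that("agreement limits cover ~95% of Gaussian differences", {
  set.seed(42)
  ref <- rnorm(1e4, 10, 2)
  test <- ref + rnorm(1e4, 0.5, 1)
  ba <- bland_altman(ref, test)
  inside <- mean(ba$differences >= ba$loa_low & ba$differences <= ba$loa_high)
  expect_gt(inside, 0.94)
  expect_lt(inside, 0.965)
})

test_that("percent change handles increases, decreases and degenerate input", {
  expect_equal(round(percent_change(33.22, 37.34), 1), 12.4)
  expect_equal(round(percent_change(5.69, 3.50, "decrease"), 1), 38.5)
  expect_identical(percent_change(7, 7), 0)
  expect_error(percent_change(0, 1), "nonzero")
})

test_that("the reference cohort means reproduce every printed improvement", {
  pc <- cohort_percent_changes()
  expect_identical(nrow(pc), 9L)
  got <- round(pc$percent_change, 1)
  names(got) <- paste(pc$metric, pc$dose, sep = "_")
  expect_identical(got[c("psnr_half", "psnr_quarter", "psnr_eighth")],
                   c(psnr_half = 12.4, psnr_quarter = 25.2, psnr_eighth = 32.1))
  expect_identical(got[c("ssim_half", "ssim_quarter", "ssim_eighth")],
                   c(ssim_half = 2.1, ssim_quarter = 4.3, ssim_eighth = 6.7))
  expect_identical(got[c("rmse_half", "rmse_quarter", "rmse_eighth")],
                   c(rmse_half = 38.5, rmse_quarter = 56.3, rmse_eighth = 59.7))
})

test_that("metrics_report collects all four metrics in one row", {
  ref <- array(runif(4 * 8 * 8, 1, 10), c(4, 8, 8))
  test <- ref + array(rnorm(length(ref), 0, 0.5), dim(ref))
  rep <- metrics_report(ref, test, label = "demo")
  expect_identical(nrow(rep), 1L)
  expect_identical(rep$label, "demo")
  expect_equal(rep$rmse, rmse(ref, test))
  expect_equal(rep$ssim, ssim_global(ref, test))
})
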