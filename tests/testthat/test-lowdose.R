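test_that("binomial thinning conserves counts exactly and honours p = 0, 1", {
  sd_proj <- small_counts(total = 2e4, seed = 3)
  res <- binomial_thin(sd_proj, 0.3, seed = 5)
  expect_identical(res$kept$counts + res$rejected$counts, sd_proj$counts)
  expect_equal(res$kept$dose_fraction, 0.3)

  expect_identical(binomial_thin(sd_proj, 1, seed = 1)$kept$counts,
                   sd_proj$counts)
  expect_true(all(binomial_thin(sd_proj, 1, seed = 1)$rejected$counts == 0))
  expect_true(all(binomial_thin(sd_proj, 0, seed = 1)$kept$counts == 0))
  expect_error(binomial_thin(sd_proj, 1.2), "probability")
})

test_that("thinning is reproducible under a fixed seed", {
  sd_proj <- small_counts(seed = 2)
  a <- binomial_thin(sd_proj, 0.5, seed = 11)
  b <- binomial_thin(sd_proj, 0.5, seed = 11)
  expect_identical(a$kept$counts, b$kept$counts)
  c <- binomial_thin(sd_proj, 0.5, seed = 12)
  expect_false(identical(a$kept$counts, c$kept$counts))
})

test_that("thinned Poisson counts stay Poisson with mean p * lambda", {
  # Poisson thinning theorem checked by Monte Carlo on high-mean bins
  pr <- project(small_phantom(), small_geometry())
  draws <- sapply(1:150, function(s) {
    sc <- sample_counts(pr, 2e5, seed = s)
    binomial_thin(sc, 0.5, seed = 1e4 + s)$kept$counts[which(sc$expected >= 60)[1:15]]
  })
  iod <- apply(draws, 1, stats::var) / rowMeans(draws)
  expect_lt(abs(mean(iod) - 1), 0.15)
})

test_that("sequential thinning composes like thinning by the product", {
  sd_proj <- small_counts(total = 5e4, seed = 6)
  kept_frac <- function(p, q, s) {
    k1 <- binomial_thin(sd_proj, p, seed = s)$kept
    sum(binomial_thin(k1, q, seed = s + 500)$kept$counts) / sum(sd_proj$counts)
  }
  fr2 <- vapply(1:40, function(s) kept_frac(0.5, 0.5, s), numeric(1))
  fr1 <- vapply(1:40, function(s) {
    sum(binomial_thin(sd_proj, 0.25, seed = 9000 + s)$kept$counts) /
      sum(sd_proj$counts)
  }, numeric(1))
  se <- sqrt(0.25 * 0.75 / sum(sd_proj$counts))
  expect_lt(abs(mean(fr2) - mean(fr1)), 4 * se / sqrt(40) * 2)
  expect_lt(abs(mean(fr2) - 0.25), 4 * se / sqrt(40))
})

test_that("per-event list-mode thinning matches per-bin thinning statistically", {
  sd_proj <- small_counts(total = 1e4, seed = 8)
  ev <- thin_events(sd_proj, 0.5, seed = 21)
  expect_identical(ev$kept$counts + ev$rejected$counts, sd_proj$counts)
  frac <- sum(ev$kept$counts) / sum(sd_proj$counts)
  expect_lt(abs(frac - 0.5), 4 * sqrt(0.25 / sum(sd_proj$counts)))
})

test_that("gate splitting partitions counts exactly with the right weights", {
  sd_proj <- small_counts(total = 5e4, seed = 4)
  g1 <- split_gates(sd_proj, 1)
  expect_identical(g1[[1]]$counts, sd_proj$counts)

  gates <- split_gates(sd_proj, 8, seed = 2)
  expect_identical(Reduce(`+`, lapply(gates, function(g) g$counts)),
                   sd_proj$counts)
  expect_identical(vapply(gates, function(g) g$gate, integer(1)), 0:7)
  fr <- vapply(gates, function(g) sum(g$counts), numeric(1)) / sum(sd_proj$counts)
  se <- sqrt(0.125 * 0.875 / sum(sd_proj$counts))
  expect_true(all(abs(fr - 0.125) < 5 * se))

  w <- c(0.5, 0.3, 0.2)
  gw <- split_gates(sd_proj, 3, gate_weights = w, seed = 3)
  frw <- vapply(gw, function(g) sum(g$counts), numeric(1)) / sum(sd_proj$counts)
  expect_true(all(abs(frw - w) < 0.02))
  expect_error(split_gates(sd_proj, 3, gate_weights = c(0.5, 0.4, 0.2)),
               "sum to 1")
})

test_that("row cropping zeroes exactly the excluded rows and is idempotent", {
  geom <- acquisition_geometry(n_views = 4L, detector_rows = 16L,
                               detector_cols = 16L)
  ph <- make_phantom(lv = lv_parameters(semi_axes_mm = c(24, 24, 30),
                                        wall_mm = 10),
                     grid_size = 16L,
                     liver = list(center = c(8.5, 8.5, 3),
                                  semi_axes_mm = c(15, 15, 8), activity = 2))
  sd_proj <- sample_counts(project(ph, geom), 2e4, seed = 5)

  full <- crop_projections(sd_proj, c(1, 16))
  expect_identical(full$counts, sd_proj$counts)

  cropped <- crop_projections(sd_proj, c(6, 16))
  removed_rows <- 1:5
  expect_true(all(cropped$counts[, removed_rows, ] == 0))
  drop <- sum(sd_proj$counts) - sum(cropped$counts)
  expect_identical(drop, sum(sd_proj$counts[, removed_rows, ]))

  twice <- crop_projections(cropped, c(6, 16))
  expect_identical(twice$counts, cropped$counts)
  expect_error(crop_projections(sd_proj, c(12, 5)), "range")
})
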