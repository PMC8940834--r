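test_that("MLEM increases the Poisson log-likelihood monotonically", {
  sd_proj <- small_counts(total = 2e4, seed = 5)
  lls <- vapply(1:6, function(it) {
    poisson_loglik(sd_proj, osem(sd_proj, n_iterations = it, n_subsets = 1))
  }, numeric(1))
  expect_true(all(diff(lls) >= -1e-9 * abs(lls[-1])))
})

test_that("reprojected totals equal measured totals after each MLEM pass", {
  sd_proj <- small_counts(total = 2e4, seed = 9)
  vol <- osem(sd_proj, n_iterations = 3, n_subsets = 1)
  geom <- sd_proj$geometry
  ops <- spectdenoise:::view_operators(geom, 16, 16)
  Xm <- matrix(vol$values, 256, 16)
  reproj <- sum(vapply(seq_len(geom$n_views), function(v) {
    sum(as.matrix(ops[[v]] %*% Xm)) * geom$pixel_mm
  }, numeric(1)))
  expect_equal(reproj, sum(sd_proj$counts), tolerance = 1e-6)
})

test_that("MLEM localises a hot voxel from noiseless projections", {
  geom <- small_geometry()
  ph <- small_phantom()
  ph$activity[] <- 0
  ph$activity[8, 8, 8] <- 5
  pr <- project(ph, geom)
  pr$counts <- array(as.integer(round(pr$expected)), dim = dim(pr$expected))
  vol <- osem(pr, n_iterations = 20, n_subsets = 1)
  expect_identical(which.max(vol$values),
                   which.max(ph$activity))
})

test_that("OSEM validates subsets, annihilates zero data, stays nonnegative", {
  sd_proj <- small_counts(total = 1e4, seed = 2)
  expect_error(osem(sd_proj, n_subsets = 3), "divide")
  expect_error(osem(sd_proj, init = matrix(0, 256, 16)), "strictly positive")
  vol <- osem(sd_proj, n_iterations = 8, n_subsets = 2)
  expect_true(all(vol$values >= 0))
  expect_identical(vol$orientation, "transaxial")

  zero <- sd_proj
  zero$counts[] <- 0L
  expect_true(all(osem(zero, n_iterations = 1, n_subsets = 1)$values == 0))
})

test_that("the Butterworth gain is 1 at DC, 0.5 at the cutoff", {
  expect_identical(butterworth_gain(0), 1)
  expect_equal(butterworth_gain(0.45), 0.5, tolerance = 1e-12)
  expect_equal(butterworth_gain(0.3, order = 4, cutoff = 0.3), 0.5,
               tolerance = 1e-12)
  expect_error(butterworth_gain(0.1, order = 0), "order")
  expect_error(butterworth_gain(0.1, cutoff = 1.5), "cutoff")
})

test_that("Butterworth filtering preserves constants and reduces variance", {
  const <- array(3, c(8, 8, 8))
  expect_equal(butterworth(const), const, tolerance = 1e-12)
  set.seed(1)
  noise <- array(rnorm(16^3), c(16, 16, 16))
  out <- butterworth(noise)
  expect_lt(stats::var(as.vector(out)), stats::var(as.vector(noise)))
  expect_equal(mean(out), mean(noise), tolerance = 1e-12)
  expect_true(is.double(out) && !is.complex(out))
})

test_that("double filtering equals filtering with the squared response", {
  set.seed(2)
  x <- array(rnorm(12^3), c(12, 12, 12))
  twice <- butterworth(butterworth(x, 6, 0.4), 6, 0.4)
  # apply H^2 directly through the frequency domain
  d <- dim(x)
  freqs <- lapply(d, spectdenoise:::fft_freqs)
  grids <- do.call(expand.grid, freqs)
  fn <- sqrt(Reduce(`+`, lapply(grids, function(f) f^2))) / 0.5
  H2 <- array(butterworth_gain(fn, 6, 0.4)^2, dim = d)
  direct <- Re(stats::fft(stats::fft(x) * H2, inverse = TRUE)) / prod(d)
  expect_equal(twice, direct, tolerance = 1e-12)
})

test_that("reorientation is exact at zero angles and composes as a rotation", {
  ph <- small_phantom()
  vol <- recon_volume(ph$activity, voxel_mm = ph$voxel_mm)
  ident <- reorient(vol, 0, 0, method = "nearest")
  expect_identical(ident$values, vol$values)
  expect_identical(ident$orientation, "SA")

  twice <- rotate_volume(rotate_volume(ph$activity, 90), 90)
  once <- rotate_volume(ph$activity, 180)
  expect_equal(twice, once, tolerance = 1e-9)
})

test_that("rotation round-trips a smooth phantom with high fidelity", {
  g <- expand.grid(x = 1:32, y = 1:32, z = 1:32)
  smooth <- array(exp(-((g$x - 16.5)^2 + (g$y - 16.5)^2 +
                          (g$z - 16.5)^2) / 60), c(32, 32, 32))
  rt <- rotate_volume(rotate_volume(smooth, 33, 20), 33, 20, inverse = TRUE)
  expect_gt(stats::cor(as.vector(rt), as.vector(smooth)), 0.99)
})

test_that("long-axis stacks are orientation-tagged permutations of the SA", {
  ph <- small_phantom()
  sa <- reorient(recon_volume(ph$activity), 0, 0)
  stacks <- long_axis_stacks(sa)
  expect_identical(stacks$VLA$orientation, "VLA")
  expect_identical(stacks$HLA$orientation, "HLA")
  expect_identical(sort(as.vector(stacks$VLA$values)),
                   sort(as.vector(sa$values)))
})
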