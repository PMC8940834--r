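test_that("the generator spec builds the published architecture", {
  spec <- gan_spec()
  expect_identical(spec$encoder_filters, c(64L, 128L, 256L, 512L, 512L, 512L))
  expect_identical(spec$decoder_filters, c(512L, 512L, 256L, 128L, 64L, 1L))
  # discriminator filters double across the three blocks after the first
  expect_identical(spec$disc_filters[-1] / spec$disc_filters[-4],
                   c(2, 2, 2))
  expect_error(gan_spec(encoder_filters = 1:3, decoder_filters = 1:4),
               "same number")

  gen <- build_generator(spec, seed = 1)
  st <- model_structure(gen)
  expect_identical(sum(st$stage == "encoder"), 6L)
  expect_identical(sum(st$stage == "decoder"), 6L)
  # 64 / 2^6 = 1: the bottleneck is a single pixel
  expect_identical(st$size_out[st$stage == "encoder"][6], 1L)
  # skips on decoders 1-5, dropout on decoder 1, sigmoid output, no pooling
  dec_layers <- st$layer[st$stage == "decoder"]
  expect_identical(sum(grepl("skip_concat", dec_layers)), 5L)
  expect_true(grepl("dropout", dec_layers[1]))
  expect_true(grepl("sigmoid", dec_layers[6]))
  expect_false(any(grepl("pool", st$layer)))
  # batch norm in encoder blocks 2-4 only
  enc_layers <- st$layer[st$stage == "encoder"]
  expect_identical(grepl("batch_norm", enc_layers),
                   c(FALSE, TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_true(grepl("relu", enc_layers[6]) && !grepl("lrelu", enc_layers[6]))

  expect_error(build_generator(spec, input_size = 60), "divisible")
})

test_that("the discriminator produces an 8x8 patch probability map", {
  disc <- build_discriminator(gan_spec(), seed = 2)
  st <- model_structure(disc)
  expect_identical(st$filters[1:4], c(48L, 96L, 192L, 384L))
  expect_identical(st$size_out, c(32L, 16L, 8L, 8L, 8L))
  expect_identical(disc$patch_size, 8L)

  N <- 2L
  X <- matrix(runif(N * 64 * 64 * 2), N * 64 * 64, 2)
  z <- disc_forward(disc, X, N, train = TRUE)
  expect_identical(dim(z), c(N * 8L * 8L, 1L))
  p <- 1 / (1 + exp(-z))
  expect_true(all(p > 0 & p < 1))
})

test_that("the generator maps a 64x64 view into (0, 1) at the same size", {
  gen <- build_generator(gan_spec(), seed = 3)
  X <- matrix(runif(64 * 64), 64 * 64, 1)
  out <- gen_forward(gen, X, 1L, train = FALSE)
  expect_identical(dim(out), c(64L * 64L, 1L))
  expect_true(all(out > 0 & out < 1))
})

test_that("backpropagation matches finite differences on a tiny network", {
  set.seed(99)
  spec <- tiny_spec()
  g <- build_generator(spec, input_size = 8L, seed = 3)
  N <- 2L
  X <- matrix(runif(N * 64), N * 64, 1)
  R <- matrix(rnorm(N * 64), N * 64, 1)
  lossfun <- function() sum(gen_forward(g, X, N, train = TRUE) * R)
  invisible(gen_forward(g, X, N, train = TRUE))
  spectdenoise:::zero_grads(spectdenoise:::gen_layers(g))
  invisible(spectdenoise:::gen_backward(g, R))
  eps <- 1e-6
  probe <- list(list(g$enc[[1]]$conv, "W", 7L),
                list(g$enc[[2]]$bn, "gamma", 3L),
                list(g$dec[[1]]$convt, "W", 41L),
                list(g$dec[[2]]$convt, "b", 1L))
  for (pr in probe) {
    ly <- pr[[1]]; nm <- pr[[2]]; i <- pr[[3]]
    p0 <- get(nm, envir = ly)
    p <- p0; p[i] <- p[i] + eps; assign(nm, p, envir = ly); lp <- lossfun()
    p[i] <- p[i] - 2 * eps; assign(nm, p, envir = ly); lm <- lossfun()
    assign(nm, p0, envir = ly)
    ana <- get(paste0("d", nm), envir = ly)[i]
    expect_equal(ana, (lp - lm) / (2 * eps), tolerance = 1e-5)
  }
})

test_that("training is bit-reproducible under a fixed seed", {
  set.seed(1)
  n <- 12L
  inputs <- array(rpois(n * 8 * 8, 5), c(n, 8, 8))
  targets <- array(rpois(n * 8 * 8, 10), c(n, 8, 8))
  pv <- paired_views(inputs, targets)
  cfg <- train_config(epochs = 3, batch_size = 4, seed = 77)
  h1 <- gan_train(pv, cfg, spec = tiny_spec(dropout_rate = 0.5))$history
  h2 <- gan_train(pv, cfg, spec = tiny_spec(dropout_rate = 0.5))$history
  expect_identical(h1, h2)
  h3 <- gan_train(pv, train_config(epochs = 3, batch_size = 4, seed = 78),
                  spec = tiny_spec(dropout_rate = 0.5))$history
  expect_false(identical(h1$l2_loss, h3$l2_loss))
})

test_that("the generator loss combines adversarial and L2 terms as 1:100", {
  cfg <- train_config()
  expect_identical(cfg$loss_weight_l2, 100)
  expect_identical(cfg$loss_weight_adv, 1)
  expect_identical(cfg$learning_rate, 0.001)
  expect_error(train_config(loss_weight_l2 = -1), "positive")
  expect_error(train_config(learning_rate = 0), "positive")
})

test_that("a pure-L2 generator autoencodes a toy set", {
  # adversarial weight 0, targets = inputs: the generator must drive its
  # reconstruction loss well below the starting point
  set.seed(5)
  geom <- acquisition_geometry(n_views = 16L, detector_rows = 16L,
                               detector_cols = 16L)
  ph <- make_phantom(lv = lv_parameters(semi_axes_mm = c(24, 24, 30),
                                        wall_mm = 10), grid_size = 16L)
  sets <- lapply(1:3, function(i) {
    sample_counts(project(ph, geom), 3e4, seed = i)
  })
  pv <- paired_views(sets, sets)
  expect_identical(pv$n, 48L)
  spec <- gan_spec(encoder_filters = c(8L, 16L, 32L, 64L),
                   decoder_filters = c(64L, 32L, 16L, 1L),
                   encoder_bn_blocks = c(2L, 3L))
  fit <- gan_train(pv, train_config(loss_weight_adv = 0, epochs = 30,
                                    seed = 11), spec = spec)
  expect_lt(fit$history$l2_loss[30], 0.1 * fit$history$l2_loss[1])
  expect_true(all(is.na(fit$history$adv_loss)))
})

test_that("denoise rescales, preserves shape and marks provenance", {
  set.seed(2)
  geom <- acquisition_geometry(n_views = 8L, detector_rows = 16L,
                               detector_cols = 16L)
  sd_proj <- small_counts(total = 3e4, seed = 6)
  low <- binomial_thin(sd_proj, 0.5, seed = 1)$kept
  pv <- paired_views(low, sd_proj)
  fit <- gan_train(pv, train_config(epochs = 2, batch_size = 4, seed = 5),
                   spec = tiny_spec(dropout_rate = 0.5))
  pred <- denoise(fit, low)
  expect_identical(dim(pred$expected), dim(sd_proj$counts))
  expect_true(all(pred$expected >= 0))
  expect_identical(pred$dose_fraction, 1)
  expect_true(pred$provenance$predicted)
  expect_identical(pred$provenance$from_dose, 0.5)
  # inference is deterministic
  expect_identical(pred$expected, denoise(fit, low)$expected)
  bad <- small_counts(seed = 1, n_views = 8L)
  bad$geometry$detector_rows <- 32L
  expect_error(denoise(fit, bad), "match")
})

test_that("a trained model survives a save/load round trip", {
  set.seed(3)
  n <- 8L
  inputs <- array(rpois(n * 8 * 8, 4), c(n, 8, 8))
  targets <- array(rpois(n * 8 * 8, 8), c(n, 8, 8))
  pv <- paired_views(inputs, targets)
  fit <- gan_train(pv, train_config(epochs = 2, batch_size = 4, seed = 9),
                   spec = tiny_spec())
  path <- withr::local_tempfile(fileext = ".rds")
  gan_save(fit, path)
  back <- gan_load(path)
  X <- matrix(runif(64), 64, 1)
  expect_identical(gen_forward(back$generator, X, 1L, train = FALSE),
                   gen_forward(fit$generator, X, 1L, train = FALSE))
  expect_identical(back$scale, fit$scale)
  expect_identical(back$history, fit$history)
})
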