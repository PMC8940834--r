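# End-to-end smoke tests use a reduced-filter network and tiny epoch counts:
# the experiment driver's contract (structure, determinism, internal
# consistency) does not depend on converged training.

small_exp_config <- function(output_dir = NULL, master_seed = 11L) {
  experiment_config(
    n_train_phantoms = 1L,
    test_groups = c(healthy = 1L, severe = 1L),
    total_counts = 5e4,
    dose_fractions = c(0.5, 0.25, 0.125),
    epochs = 1L, batch_size = 8L,
    spec = gan_spec(encoder_filters = c(4L, 8L, 8L, 8L, 8L, 8L),
                    decoder_filters = c(8L, 8L, 8L, 8L, 4L, 1L),
                    disc_filters = c(4L, 8L, 16L, 16L)),
    recon_iterations = 2L, recon_subsets = 2L,
    do_recon = TRUE, output_dir = output_dir, master_seed = master_seed)
}

test_that("the experiment driver emits every arm with consistent reporting", {
  out_dir <- withr::local_tempdir()
  cfg <- small_exp_config(output_dir = out_dir)
  cfg$n_gates <- 4L
  res <- run_experiment(cfg, quiet = TRUE)

  # gated split of each test standard-dose set reconstructs it exactly
  expect_identical(length(res$gates), 2L)
  g1 <- res$gates[[1]]
  expect_identical(length(g1), 4L)
  expect_identical(vapply(g1, function(g) g$gate, integer(1)), 0:3)
  same_test <- simulate_cohort(
    rep(names(cfg$test_groups), times = cfg$test_groups),
    acquisition_geometry(), cfg$total_counts,
    master_seed = substream_seed(cfg$master_seed, "test_cohort"))
  expect_identical(Reduce(`+`, lapply(g1, function(g) g$counts)),
                   same_test$standard[[1]]$counts)

  expect_setequal(unique(res$metrics$dose), c("half", "quarter", "eighth"))
  expect_setequal(unique(res$metrics$label), c("low_dose", "predicted"))
  expect_identical(nrow(res$metrics), 2L * 2L * 3L) # 2 phantoms x 2 arms x 3 doses
  expect_setequal(unique(res$scores$arm),
                  c("standard", "low_half", "pred_half", "low_quarter",
                    "pred_quarter", "low_eighth", "pred_eighth"))

  # summary percent changes equal percent_change applied to its own means
  for (d in c("half", "quarter", "eighth")) {
    m <- res$arm_summary
    lo <- m[m$dose == d & m$label == "low_dose", ]
    pr <- m[m$dose == d & m$label == "predicted", ]
    pc <- res$percent_changes[res$percent_changes$dose == d, ]
    expect_equal(pc$psnr, percent_change(lo$psnr_db, pr$psnr_db))
    expect_equal(pc$rmse, percent_change(lo$rmse, pr$rmse, "decrease"))
    expect_equal(pc$ssim, percent_change(lo$ssim, pr$ssim))
  }

  expect_true(file.exists(file.path(out_dir, "summary.json")))
  expect_true(file.exists(file.path(out_dir, "metrics.csv")))
  expect_gt(length(Sys.glob(file.path(out_dir, "*.sproj"))), 0)
  # written projections are readable
  back <- read_sproj(Sys.glob(file.path(out_dir, "*_low_half.sproj"))[1])
  expect_identical(back$dose_fraction, 0.5)
})

test_that("identical master seeds give byte-identical summaries", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg1 <- small_exp_config(output_dir = d1)
  cfg1$do_recon <- FALSE
  cfg2 <- small_exp_config(output_dir = d2)
  cfg2$do_recon <- FALSE
  run_experiment(cfg1, quiet = TRUE)
  run_experiment(cfg2, quiet = TRUE)
  s1 <- readBin(file.path(d1, "summary.json"), "raw",
                file.info(file.path(d1, "summary.json"))$size)
  s2 <- readBin(file.path(d2, "summary.json"), "raw",
                file.info(file.path(d2, "summary.json"))$size)
  expect_identical(s1, s2)
})

test_that("cohort simulation is risk-stratified and seed-stable", {
  co <- simulate_cohort(c("healthy", "severe"), total_counts = 2e4,
                        geometry = small_geometry(),
                        master_seed = 5L)
  expect_identical(co$id, c("P001", "P002"))
  expect_identical(sum(co$phantom[[1]]$masks$defect), 0L)
  expect_gt(sum(co$phantom[[2]]$masks$defect), 0L)
  co2 <- simulate_cohort(c("healthy", "severe"), total_counts = 2e4,
                         geometry = small_geometry(),
                         master_seed = 5L)
  expect_identical(co$standard[[1]]$counts, co2$standard[[1]]$counts)
  expect_error(simulate_cohort(c("healthy", "low"), ids = c("a", "a")),
               "unique")
})

test_that("substream seeds are deterministic, distinct and in range", {
  s1 <- substream_seed(42, "thinning", 1)
  expect_identical(s1, substream_seed(42, "thinning", 1))
  expect_false(s1 == substream_seed(42, "thinning", 2))
  expect_false(s1 == substream_seed(42, "poisson", 1))
  expect_false(s1 == substream_seed(43, "thinning", 1))
  streams <- vapply(1:500, function(i) substream_seed(1, "s", i), integer(1))
  expect_true(all(streams >= 1 & streams <= 2^31 - 2))
  expect_identical(length(unique(streams)), 500L)
})
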