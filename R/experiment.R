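#' Configuration of an end-to-end denoising experiment
#'
#' Bundles every tunable of the pipeline — cohort composition, count level,
#' dose arms, reconstruction settings, network architecture and training
#' hyperparameters — plus the single master seed from which all random
#' substreams (phantoms, Poisson sampling, thinning, training) are derived.
#'
#' @param n_train_phantoms Number of training phantoms (32 projection views
#'   each become 32 training pairs).
#' @param test_groups Named integer vector: test phantoms per risk group
#'   (`healthy`, `low`, `intermediate`, `severe`).
#' @param total_counts Expected standard-dose counts per non-gated
#'   projection set.
#' @param dose_fractions Reduced-dose arms to simulate.
#' @param n_gates If not `NULL`, additionally split the standard-dose test
#'   sets into this many cardiac gates.
#' @param epochs,batch_size,learning_rate,loss_weight_l2,loss_weight_adv
#'   Training hyperparameters (see [train_config()]).
#' @param spec A [gan_spec()].
#' @param recon_iterations,recon_subsets,butterworth_order,butterworth_cutoff
#'   Reconstruction settings.
#' @param do_recon Reconstruct the test arms and compute image-space
#'   metrics and segment scores (slower; default `TRUE`).
#' @param output_dir Directory for projections, volumes and reports; created
#'   if missing. `NULL` keeps everything in memory.
#' @param master_seed Master seed for the whole experiment.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(n_train_phantoms = 2L,
                              test_groups = c(healthy = 1L, low = 1L,
                                              intermediate = 1L, severe = 1L),
                              total_counts = 2e5,
                              dose_fractions = c(0.5, 0.25, 0.125),
                              n_gates = NULL,
                              epochs = 10L, batch_size = 8L,
                              learning_rate = 0.001,
                              loss_weight_l2 = 100, loss_weight_adv = 1,
                              spec = gan_spec(),
                              recon_iterations = 8L, recon_subsets = 2L,
                              butterworth_order = 10, butterworth_cutoff = 0.45,
                              do_recon = TRUE,
                              output_dir = NULL, master_seed = 1L) {
  if (any(dose_fractions <= 0) || any(dose_fractions > 1)) {
    abort_param("`dose_fractions` must lie in (0, 1]")
  }
  structure(as.list(environment()), class = "experiment_config")
}

risk_levels <- c("healthy", "low", "intermediate", "severe")

#' Generate a random phantom for a risk group
#'
#' Healthy phantoms have a uniform shell; increasing risk adds perfusion
#' defects of increasing severity and angular extent, with randomised
#' location and a mildly randomised LV orientation.
#'
#' @param risk One of `"healthy"`, `"low"`, `"intermediate"`, `"severe"`.
#' @param seed Integer seed (deterministic phantom per `(risk, seed)`).
#' @param grid_size,voxel_mm Grid settings passed to [make_phantom()].
#' @return A [make_phantom()] object.
#' @export
random_phantom <- function(risk = "healthy", seed = 1L, grid_size = 64L,
                           voxel_mm = 6.4) {
  risk <- match.arg(risk, risk_levels)
  with_seed(seed, {
    axis <- c(stats::runif(1, -0.35, 0.35), stats::runif(1, -0.35, 0.35), 1)
    ab <- stats::runif(1, 28, 36) # LV outer short semi-axes, mm
    cc <- stats::runif(1, 42, 54) # long semi-axis, mm
    n <- as.integer(grid_size)
    center <- rep((n + 1) / 2, 3) +
      c(stats::runif(2, -2, 2), stats::runif(1, -1, 1))
    lv <- lv_parameters(center = center, axis = axis,
                        semi_axes_mm = c(ab, ab, cc),
                        wall_mm = stats::runif(1, 8, 12),
                        base_cut = stats::runif(1, 0.2, 0.4))
    sev <- switch(risk, healthy = 0, low = stats::runif(1, 0.25, 0.4),
                  intermediate = stats::runif(1, 0.45, 0.65),
                  severe = stats::runif(1, 0.75, 1))
    span <- switch(risk, healthy = 0, low = stats::runif(1, 50, 70),
                   intermediate = stats::runif(1, 70, 100),
                   severe = stats::runif(1, 90, 130))
    defects <- list()
    if (sev > 0) {
      a0 <- stats::runif(1, 0, 360)
      z0 <- stats::runif(1, 0.15, 0.5)
      defects <- list(lv_defect(angle_deg = c(a0, a0 + span),
                                axial = c(z0, min(z0 + stats::runif(1, 0.3, 0.5), 1)),
                                severity = sev))
      # severe disease often shows a second, milder territory
      if (risk == "severe" && stats::runif(1) < 0.5) {
        a1 <- (a0 + stats::runif(1, 120, 240)) %% 360
        defects <- c(defects, list(lv_defect(
          angle_deg = c(a1, a1 + stats::runif(1, 40, 70)),
          axial = c(stats::runif(1, 0.2, 0.5), stats::runif(1, 0.6, 0.9)),
          severity = stats::runif(1, 0.3, 0.5))))
      }
    }
    make_phantom(lv = lv, defects = defects, grid_size = grid_size,
                 voxel_mm = voxel_mm, seed = seed)
  })
}

#' Simulate a cohort of standard-dose acquisitions
#'
#' @param risks Character vector of risk groups, one phantom each.
#' @param geometry An [acquisition_geometry()].
#' @param total_counts Expected counts per standard-dose projection set.
#' @param master_seed Master seed; phantom `i` uses substreams
#'   `("phantom", i)` and `("poisson", i)`.
#' @param ids Optional character ids (default `P001`, `P002`, ...).
#' @return A tibble with columns `id`, `risk`, and list-columns `phantom`
#'   and `standard` (the sampled standard-dose [projection_set()]s).
#' @export
simulate_cohort <- function(risks, geometry = acquisition_geometry(),
                            total_counts = 2e5, master_seed = 1L,
                            ids = NULL) {
  ids <- ids %||% sprintf("P%03d", seq_along(risks))
  if (anyDuplicated(ids)) abort_param("cohort ids must be unique")
  rows <- purrr::map(seq_along(risks), function(i) {
    ph <- random_phantom(risks[i], seed = substream_seed(master_seed, "phantom", i),
                         grid_size = geometry$detector_cols,
                         voxel_mm = geometry$pixel_mm)
    sd <- sample_counts(project(ph, geometry), total_counts,
                        seed = substream_seed(master_seed, "poisson", i))
    list(id = ids[i], risk = risks[i], phantom = ph, standard = sd)
  })
  tibble::tibble(
    id = purrr::map_chr(rows, "id"),
    risk = purrr::map_chr(rows, "risk"),
    phantom = purrr::map(rows, "phantom"),
    standard = purrr::map(rows, "standard")
  )
}

#' Validate a cohort manifest
#'
#' @param manifest A data frame with at least `id` and `risk` columns, plus
#'   optional file-path columns (every referenced file must exist).
#' @return The manifest, invisibly; errors on duplicate ids, unknown risk
#'   groups or missing files.
#' @export
validate_manifest <- function(manifest) {
  if (anyDuplicated(manifest$id)) {
    abort_param("manifest ids must be unique")
  }
  if (!all(manifest$risk %in% risk_levels)) {
    abort_param("unknown risk group in manifest")
  }
  path_cols <- grep("_path$", names(manifest), value = TRUE)
  for (col in path_cols) {
    missing <- !file.exists(manifest[[col]])
    if (any(missing)) {
      abort_param(sprintf("missing file(s) in manifest column %s: %s", col,
                          paste(manifest[[col]][missing], collapse = ", ")))
    }
  }
  invisible(manifest)
}

#' Run the full low-dose denoising experiment
#'
#' Simulates training and test cohorts, thins each standard-dose acquisition
#' to every reduced-dose arm, trains one conditional GAN per arm, denoises
#' the held-out test sets, and evaluates: projection-space image-quality
#' metrics for the low-dose and predicted arms against the standard-dose
#' reference, the corresponding percent changes, and (with `do_recon`)
#' OSEM + Butterworth reconstructions with image-space metrics, 17-segment
#' summed scores and their Bland-Altman agreement. Fully deterministic given
#' the master seed.
#'
#' @param config An [experiment_config()].
#' @param quiet Suppress per-stage log messages.
#' @return A list of class `spect_experiment` with tibbles `metrics`
#'   (per test phantom x arm), `arm_summary` (per-arm means),
#'   `percent_changes`, `scores` (summed segment scores, if reconstructed),
#'   `agreement` (Bland-Altman on summed scores), the trained `fits`, and
#'   `config`.
#' @export
run_experiment <- function(config = experiment_config(), quiet = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  geom <- acquisition_geometry()
  ms <- config$master_seed

  say("stage phantom: %d training + %d test phantoms (master seed %d)",
      config$n_train_phantoms, sum(config$test_groups), ms)
  train_risks <- rep(risk_levels, length.out = config$n_train_phantoms)
  train <- simulate_cohort(train_risks, geom, config$total_counts,
                           master_seed = substream_seed(ms, "train_cohort"),
                           ids = sprintf("T%03d", seq_len(config$n_train_phantoms)))
  test_risks <- rep(names(config$test_groups), times = config$test_groups)
  test <- simulate_cohort(test_risks, geom, config$total_counts,
                          master_seed = substream_seed(ms, "test_cohort"))

  arms <- list()
  fits <- list()
  metrics <- list()
  for (p in config$dose_fractions) {
    arm <- dose_label(p)
    say("stage thinning: dose fraction %g (%s)", p, arm)
    tr_low <- purrr::imap(train$standard, function(sd, i) {
      binomial_thin(sd, p, seed = substream_seed(ms, paste0("thin_train_", arm), i))$kept
    })
    te_low <- purrr::imap(test$standard, function(sd, i) {
      binomial_thin(sd, p, seed = substream_seed(ms, paste0("thin_test_", arm), i))$kept
    })
    say("stage training: %s model, %d pairs, %d epochs", arm,
        32L * length(tr_low), config$epochs)
    cfg <- train_config(loss_weight_l2 = config$loss_weight_l2,
                        loss_weight_adv = config$loss_weight_adv,
                        learning_rate = config$learning_rate,
                        epochs = config$epochs,
                        batch_size = config$batch_size,
                        seed = substream_seed(ms, paste0("training_", arm)))
    fit <- gan_train(paired_views(tr_low, train$standard), cfg,
                     spec = config$spec)
    preds <- purrr::map(te_low, ~denoise(fit, .x))
    fits[[arm]] <- fit
    arms[[arm]] <- list(p = p, low = te_low, pred = preds)
    metrics[[arm]] <- dplyr::bind_rows(purrr::pmap(
      list(test$id, test$standard, te_low, preds),
      function(id, sd, low, pred) {
        ref <- proj_values(sd)
        dplyr::bind_rows(
          metrics_report(ref, proj_values(low), label = "low_dose"),
          metrics_report(ref, proj_values(pred), label = "predicted")
        ) |> dplyr::mutate(id = id, dose = arm, .before = 1)
      }))
  }
  metrics <- dplyr::bind_rows(metrics)

  arm_summary <- metrics |>
    dplyr::group_by(.data$dose, .data$label) |>
    dplyr::summarise(dplyr::across(c("psnr_db", "rmse", "ssim", "pearson_rho"),
                                   mean), .groups = "drop")
  percent_changes <- arm_summary |>
    tidyr::pivot_wider(names_from = "label",
                       values_from = c("psnr_db", "rmse", "ssim",
                                       "pearson_rho")) |>
    dplyr::transmute(
      dose = .data$dose,
      psnr = percent_change(.data$psnr_db_low_dose, .data$psnr_db_predicted),
      ssim = percent_change(.data$ssim_low_dose, .data$ssim_predicted),
      rmse = percent_change(.data$rmse_low_dose, .data$rmse_predicted,
                            direction = "decrease"))

  scores <- agreement <- NULL
  if (isTRUE(config$do_recon)) {
    say("stage recon: OSEM %d it x %d subsets + Butterworth (%g, %g)",
        config$recon_iterations, config$recon_subsets,
        config$butterworth_order, config$butterworth_cutoff)
    rec_score <- function(proj, axis) {
      vol <- osem(proj, config$recon_iterations, config$recon_subsets)
      vol <- butterworth(vol, config$butterworth_order,
                         config$butterworth_cutoff)
      # short-axis reorientation using the phantom's known long axis
      sa <- reorient(vol, azimuth_deg = atan2(axis[2], axis[1]) * 180 / pi,
                     elevation_deg = acos(axis[3]) * 180 / pi)
      segment_scores(sa)$summed_score
    }
    score_rows <- purrr::pmap(list(test$id, seq_len(nrow(test))),
                              function(id, i) {
      ax <- test$phantom[[i]]$lv_params$axis
      labels <- c("standard",
                  as.vector(rbind(paste0("low_", names(arms)),
                                  paste0("pred_", names(arms)))))
      values <- c(rec_score(test$standard[[i]], ax),
                  unlist(lapply(names(arms), function(a) {
                    c(rec_score(arms[[a]]$low[[i]], ax),
                      rec_score(arms[[a]]$pred[[i]], ax))
                  })))
      tibble::tibble(id = id, arm = labels, summed_score = values)
    })
    scores <- dplyr::bind_rows(score_rows)
    if (nrow(test) >= 2L) {
      ref_scores <- scores$summed_score[scores$arm == "standard"]
      agreement <- purrr::map_dfr(setdiff(unique(scores$arm), "standard"),
        function(a) {
          ba <- bland_altman(ref_scores, scores$summed_score[scores$arm == a])
          dplyr::mutate(glance(ba), arm = a, .before = 1)
        })
    }
  }

  gates <- NULL
  if (!is.null(config$n_gates)) {
    say("stage gating: splitting test standard-dose sets into %d gates",
        config$n_gates)
    gates <- purrr::imap(test$standard, function(sd, i) {
      split_gates(sd, config$n_gates,
                  seed = substream_seed(ms, "gating", i))
    })
    names(gates) <- test$id
  }

  out <- structure(
    list(metrics = metrics, arm_summary = arm_summary,
         percent_changes = percent_changes, scores = scores,
         agreement = agreement, gates = gates, fits = fits, config = config,
         test_manifest = validate_manifest(test[, c("id", "risk")])),
    class = "spect_experiment")

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    say("stage output: writing reports to %s", config$output_dir)
    utils::write.csv(metrics, file.path(config$output_dir, "metrics.csv"),
                     row.names = FALSE)
    summary_list <- list(
      master_seed = ms,
      arm_summary = arm_summary,
      percent_changes = percent_changes,
      scores = scores,
      agreement = agreement)
    jsonlite::write_json(summary_list,
                         file.path(config$output_dir, "summary.json"),
                         auto_unbox = TRUE, digits = 10, null = "null")
    for (arm in names(arms)) {
      for (i in seq_len(nrow(test))) {
        write_sproj(arms[[arm]]$low[[i]],
                    file.path(config$output_dir,
                              sprintf("%s_low_%s.sproj", test$id[i], arm)))
        write_sproj(arms[[arm]]$pred[[i]],
                    file.path(config$output_dir,
                              sprintf("%s_pred_%s.sproj", test$id[i], arm)))
      }
    }
  }
  out
}

dose_label <- function(p) {
  if (isTRUE(all.equal(p, 0.5))) return("half")
  if (isTRUE(all.equal(p, 0.25))) return("quarter")
  if (isTRUE(all.equal(p, 0.125))) return("eighth")
  paste0("p", format(p))
}

#' @export
print.spect_experiment <- function(x, ...) {
  cat("<spect_experiment>\n")
  print(x$arm_summary)
  cat("percent changes (predicted vs low-dose):\n")
  print(x$percent_changes)
  invisible(x)
}
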