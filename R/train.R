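#' Assemble paired low-dose / standard-dose training views
#'
#' Collects matching projection views from paired projection sets (or plain
#' arrays) and records the single global normalisation constant — the
#' maximum standard-dose view count over the training set — that maps both
#' arms into the (0, 1) range required by the generator's sigmoid output.
#' Each 2D view is one training sample: the 32 views of one acquisition
#' contribute 32 pairs.
#'
#' @param inputs,targets Lists of [projection_set()]s (paired element-wise),
#'   or 3D arrays `[n_views, rows, cols]`.
#' @param scale Optional normalisation constant; defaults to the maximum
#'   target value.
#' @return An object of class `paired_views` with fields `input`, `target`
#'   (matrices, one flattened view per column), `size`, `n`, `scale`.
#' @export
paired_views <- function(inputs, targets, scale = NULL) {
  flat <- function(x) {
    if (inherits(x, "projection_set")) x <- x$counts %||% x$expected
    if (length(dim(x)) != 3L) abort_param("views must be [n_views, rows, cols]")
    if (dim(x)[2] != dim(x)[3]) abort_param("views must be square")
    matrix(aperm(x, c(2, 3, 1)), dim(x)[2]^2, dim(x)[1])
  }
  if (inherits(inputs, "projection_set") || is.array(inputs)) inputs <- list(inputs)
  if (inherits(targets, "projection_set") || is.array(targets)) targets <- list(targets)
  Xi <- do.call(cbind, lapply(inputs, flat))
  Ti <- do.call(cbind, lapply(targets, flat))
  if (!identical(dim(Xi), dim(Ti))) {
    abort_param("inputs and targets must pair one-to-one")
  }
  scale <- scale %||% max(Ti)
  if (scale <= 0) abort_param("normalisation constant must be positive")
  structure(list(input = Xi, target = Ti,
                 size = as.integer(sqrt(nrow(Xi))), n = ncol(Xi),
                 scale = scale),
            class = "paired_views")
}

#' @export
print.paired_views <- function(x, ...) {
  cat(sprintf("<paired_views> %d pairs of %dx%d views, scale %.4g\n",
              x$n, x$size, x$size, x$scale))
  invisible(x)
}

#' Train the conditional GAN
#'
#' Alternating adversarial training: each minibatch first updates the
#' discriminator with binary cross-entropy on (real, generated) pairs, then
#' updates the generator on the weighted sum of the adversarial loss and the
#' L2-norm loss against the standard-dose target (100/1 in favour of L2 by
#' default). With `loss_weight_adv = 0` the discriminator is skipped and the
#' generator trains as a plain L2 regressor. Training is fully seeded:
#' identical `(pairs, config, spec)` give an identical loss history.
#'
#' @param pairs A [paired_views()] training set.
#' @param config A [train_config()].
#' @param spec A [gan_spec()].
#' @param quiet Suppress the per-epoch progress line.
#' @return An object of class `gan_fit`: the trained generator and
#'   discriminator, the normalisation constant and a per-epoch loss history
#'   (see [tidy.gan_fit()]).
#' @export
gan_train <- function(pairs, config = train_config(), spec = gan_spec(),
                      quiet = TRUE) {
  stopifnot(inherits(pairs, "paired_views"))
  if (pairs$n < 1L) abort_param("need at least one training pair")
  npix <- pairs$size^2
  gen <- build_generator(spec, input_size = pairs$size,
                         seed = substream_seed(config$seed, "gen_init"))
  use_disc <- config$loss_weight_adv > 0
  disc <- if (use_disc) {
    build_discriminator(spec, input_size = pairs$size,
                        seed = substream_seed(config$seed, "disc_init"))
  }
  gl <- gen_layers(gen)
  dl <- if (use_disc) disc_layers(disc)
  Xn <- pairs$input / pairs$scale
  Tn <- pairs$target / pairs$scale
  # scale-calibrated start: the sigmoid output layer's bias is initialised
  # to the logit of the mean normalised target, so the generator begins at
  # the data's global count scale instead of 0.5 everywhere
  out_bias <- stats::qlogis(min(max(mean(Tn), 1e-4), 1 - 1e-4))
  gen$dec[[gen$nb]]$convt$b[] <- out_bias

  history <- vector("list", config$epochs)
  with_seed(substream_seed(config$seed, "training"), {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(pairs$n)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      l2s <- advs <- dls <- numeric(length(batches))
      for (bi in seq_along(batches)) {
        idx <- batches[[bi]]
        nb <- length(idx)
        Xb <- matrix(Xn[, idx], nb * npix, 1)
        Tb <- matrix(Tn[, idx], nb * npix, 1)

        fake <- gen_forward(gen, Xb, nb, train = TRUE)

        if (use_disc) {
          zero_grads(dl)
          Zr <- disc_forward(disc, cbind(Xb, Tb), nb, train = TRUE)
          br <- bce_logits(Zr, 1)
          disc_backward(disc, 0.5 * br$dz)
          Zf <- disc_forward(disc, cbind(Xb, fake), nb, train = TRUE)
          bf <- bce_logits(Zf, 0)
          disc_backward(disc, 0.5 * bf$dz)
          adam_step(dl, config$learning_rate)
          dls[bi] <- 0.5 * (br$loss + bf$loss)

          zero_grads(dl)
          Zf2 <- disc_forward(disc, cbind(Xb, fake), nb, train = TRUE)
          ba <- bce_logits(Zf2, 1)
          dIn <- disc_backward(disc, config$loss_weight_adv * ba$dz)
          dFake_adv <- dIn[, 2, drop = FALSE]
          advs[bi] <- ba$loss
        } else {
          dFake_adv <- 0
        }

        diff <- fake - Tb
        l2s[bi] <- mean(diff^2)
        if (!is.finite(l2s[bi])) {
          stop(sprintf("training diverged (non-finite L2 loss at epoch %d)", ep),
               call. = FALSE)
        }
        dFake <- dFake_adv + config$loss_weight_l2 * 2 * diff / length(diff)
        zero_grads(gl)
        gen_backward(gen, dFake)
        adam_step(gl, config$learning_rate)
      }
      history[[ep]] <- tibble::tibble(
        epoch = ep, l2_loss = mean(l2s),
        adv_loss = if (use_disc) mean(advs) else NA_real_,
        disc_loss = if (use_disc) mean(dls) else NA_real_)
      if (!quiet) {
        message(sprintf("epoch %3d | L2 %.5f | adv %.4f | D %.4f", ep,
                        mean(l2s), mean(advs), mean(dls)))
      }
    }
  })
  structure(
    list(generator = gen, discriminator = disc, spec = spec, config = config,
         scale = pairs$scale, input_size = pairs$size,
         history = dplyr::bind_rows(history)),
    class = "gan_fit"
  )
}

#' @export
print.gan_fit <- function(x, ...) {
  cat(sprintf(
    "<gan_fit> %d epochs, final L2 loss %.5f, normalisation constant %.4g\n",
    nrow(x$history), x$history$l2_loss[nrow(x$history)], x$scale))
  invisible(x)
}

#' Per-epoch loss history of a trained GAN
#'
#' @param x A [gan_train()] fit.
#' @param ... Unused.
#' @return A tibble with columns `epoch`, `l2_loss`, `adv_loss`, `disc_loss`.
#' @method tidy gan_fit
#' @export
tidy.gan_fit <- function(x, ...) x$history

#' One-row summary of a trained GAN
#'
#' @param x A [gan_train()] fit.
#' @param ... Unused.
#' @return A one-row tibble: epochs, first/final L2 loss, loss weights and
#'   the normalisation constant.
#' @method glance gan_fit
#' @export
glance.gan_fit <- function(x, ...) {
  tibble::tibble(
    epochs = nrow(x$history),
    l2_first = x$history$l2_loss[1],
    l2_final = x$history$l2_loss[nrow(x$history)],
    loss_weight_l2 = x$config$loss_weight_l2,
    loss_weight_adv = x$config$loss_weight_adv,
    scale = x$scale
  )
}

#' Training-loss curve
#'
#' @param object A [gan_train()] fit.
#' @param ... Unused.
#' @return A ggplot of the per-epoch generator L2 loss (log scale).
#' @method autoplot gan_fit
#' @export
autoplot.gan_fit <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(x = .data$epoch, y = .data$l2_loss)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "generator L2 loss") +
    ggplot2::theme_minimal()
}

#' Predict standard-dose projections from low-dose input
#'
#' Normalises each view by the model's stored constant, passes it through
#' the trained generator (inference mode: running batch-norm statistics, no
#' dropout) and scales back to counts. The result is real-valued and
#' nonnegative, carried in the `expected` slot of the returned projection
#' set with `dose_fraction = 1` and provenance marking it as a prediction.
#'
#' @param fit A [gan_train()] fit.
#' @param proj A [projection_set()] whose detector matrix matches the
#'   training geometry.
#' @return A [projection_set()] holding the predicted standard-dose views.
#' @export
denoise <- function(fit, proj) {
  stopifnot(inherits(fit, "gan_fit"), inherits(proj, "projection_set"))
  geom <- proj$geometry
  if (geom$detector_rows != fit$input_size ||
      geom$detector_cols != fit$input_size) {
    abort_param("projection matrix does not match the trained input size")
  }
  arr <- proj$counts %||% proj$expected
  N <- geom$n_views
  X <- matrix(aperm(arr, c(2, 3, 1)), fit$input_size^2 * N, 1) / fit$scale
  out <- gen_forward(fit$generator, X, N, train = FALSE) * fit$scale
  pred <- aperm(array(out, dim = c(fit$input_size, fit$input_size, N)),
                c(3, 1, 2))
  pred[pred < 0] <- 0
  projection_set(expected = pred, geometry = geom, dose_fraction = 1,
                 provenance = c(proj$provenance,
                                list(predicted = TRUE,
                                     from_dose = proj$dose_fraction)))
}

#' Projection values for metric computation
#'
#' Counts if present, otherwise the expected (or predicted) grid.
#'
#' @param proj A [projection_set()].
#' @return A numeric array `[n_views, rows, cols]`.
#' @export
proj_values <- function(proj) proj$counts %||% proj$expected

#' Save / load a trained GAN
#'
#' Clears the transient forward-pass caches and serialises the fit (weights,
#' architecture, training configuration and normalisation constant).
#'
#' @param fit A [gan_train()] fit.
#' @param path Destination file.
#' @return `gan_save` returns `path` invisibly; `gan_load` the restored fit.
#' @export
gan_save <- function(fit, path) {
  for (ly in c(gen_layers(fit$generator),
               if (!is.null(fit$discriminator)) disc_layers(fit$discriminator))) {
    for (nm in c("Xcol", "X", "xhat", "inv", "mask", "y", "N")) {
      if (!is.null(ly[[nm]])) assign(nm, NULL, envir = ly)
    }
  }
  fit$generator$e_out <- NULL
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname gan_save
#' @export
gan_load <- function(path) readRDS(path)
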