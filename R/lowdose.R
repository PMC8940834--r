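#' Simulate a reduced-dose acquisition by binomial thinning
#'
#' Each detected count is independently kept with probability `p` and
#' rejected otherwise, exactly emulating per-event selection from a
#' list-mode acquisition: for a bin holding `n` counts the kept count is a
#' Binomial(n, p) draw and the rejected count is its complement, so
#' `kept + rejected` reconstructs the parent bin-for-bin. Thinning a
#' Poisson(lambda) bin yields a Poisson(p * lambda) bin, which is what makes
#' the kept set a faithful low-dose acquisition. Presets `p = 0.5, 0.25,
#' 0.125` correspond to half-, quarter- and one-eighth-dose studies.
#'
#' @param proj A [projection_set()] with `counts` set.
#' @param p Retention probability in `[0, 1]`.
#' @param seed Integer seed; the same `(proj, p, seed)` gives an identical
#'   result.
#' @return A list of class `thin_result` with elements `kept` and `rejected`
#'   (both [projection_set()]s), `p` and `seed`. `kept$dose_fraction` is the
#'   parent dose fraction times `p`.
#' @examples
#' geom <- acquisition_geometry(n_views = 4, detector_rows = 16,
#'                              detector_cols = 16)
#' ph <- make_phantom(grid_size = 16, lv = lv_parameters(semi_axes_mm =
#'   c(24, 24, 30), wall_mm = 8))
#' sd_proj <- sample_counts(project(ph, geom), 5e4, seed = 7)
#' half <- binomial_thin(sd_proj, 0.5, seed = 1)
#' sum(half$kept$counts) + sum(half$rejected$counts) == sum(sd_proj$counts)
#' @export
binomial_thin <- function(proj, p, seed = 1L) {
  assert_scalar_prob(p, "p")
  if (is.null(proj$counts)) abort_param("`proj` has no counts to thin")
  n <- proj$counts
  kept <- with_seed(seed, stats::rbinom(length(n), as.vector(n), p))
  kept <- array(as.integer(kept), dim = dim(n))
  rejected <- n - kept
  exp_kept <- if (!is.null(proj$expected)) proj$expected * p
  exp_rej <- if (!is.null(proj$expected)) proj$expected * (1 - p)
  prov <- c(proj$provenance, list(thin_seed = as.integer(seed), thin_p = p))
  structure(
    list(
      kept = projection_set(counts = kept, expected = exp_kept,
                            geometry = proj$geometry,
                            dose_fraction = max(proj$dose_fraction * p, 1e-12),
                            gate = proj$gate, n_gates = proj$n_gates,
                            provenance = prov),
      rejected = projection_set(counts = rejected, expected = exp_rej,
                                geometry = proj$geometry,
                                dose_fraction =
                                  max(proj$dose_fraction * (1 - p), 1e-12),
                                gate = proj$gate, n_gates = proj$n_gates,
                                provenance = prov),
      p = p, seed = as.integer(seed)
    ),
    class = "thin_result"
  )
}

#' @export
print.thin_result <- function(x, ...) {
  cat(sprintf("<thin_result> p = %g, kept %s of %s counts\n", x$p,
              format(sum(x$kept$counts), big.mark = ","),
              format(sum(x$kept$counts) + sum(x$rejected$counts),
                     big.mark = ",")))
  invisible(x)
}

#' Split counts into cardiac gates
#'
#' Partitions every bin's counts across `n_gates` cardiac-cycle intervals by
#' a multinomial draw with the given gate weights (uniform by default, i.e.
#' each gate holds 1/8 of the events for an 8-gate study). The gate grids sum
#' back to the parent exactly.
#'
#' @param proj A [projection_set()] with `counts` set.
#' @param n_gates Number of gates (default 8).
#' @param gate_weights Nonnegative weights of length `n_gates` summing to 1.
#' @param seed Integer seed.
#' @return A list of `n_gates` [projection_set()]s with `gate` set to
#'   `0:(n_gates-1)`.
#' @export
split_gates <- function(proj, n_gates = 8L, gate_weights = NULL, seed = 1L) {
  if (is.null(proj$counts)) abort_param("`proj` has no counts to gate")
  if (n_gates < 1L) abort_param("`n_gates` must be >= 1")
  w <- gate_weights %||% rep(1 / n_gates, n_gates)
  if (length(w) != n_gates || any(w < 0)) {
    abort_param("`gate_weights` must be nonnegative, length `n_gates`")
  }
  if (abs(sum(w) - 1) > 1e-8) {
    abort_param("`gate_weights` must sum to 1")
  }
  if (n_gates == 1L) {
    out <- proj
    out$gate <- 0L
    out$n_gates <- 1L
    return(list(out))
  }
  n <- as.vector(proj$counts)
  # sequential binomial construction of a multinomial draw, vectorised per
  # gate: gate g gets Binomial(remaining, w_g / remaining_weight)
  gates <- matrix(0L, length(n), n_gates)
  with_seed(seed, {
    remaining <- n
    wrem <- sum(w)
    for (g in seq_len(n_gates - 1L)) {
      pg <- if (wrem > 0) min(w[g] / wrem, 1) else 0
      draw <- stats::rbinom(length(remaining), remaining, pg)
      gates[, g] <- draw
      remaining <- remaining - draw
      wrem <- wrem - w[g]
    }
    gates[, n_gates] <- remaining
  })
  lapply(seq_len(n_gates), function(g) {
    projection_set(
      counts = array(gates[, g], dim = dim(proj$counts)),
      expected = if (!is.null(proj$expected)) proj$expected * w[g],
      geometry = proj$geometry,
      dose_fraction = proj$dose_fraction,
      gate = g - 1L, n_gates = as.integer(n_gates),
      provenance = c(proj$provenance, list(gate_seed = as.integer(seed)))
    )
  })
}

#' Crop projection rows
#'
#' Zeroes all detector rows outside `row_range`, emulating the manual crop
#' used to exclude sub-diaphragmatic (liver) activity from cardiac
#' projections. The grid shape is preserved so that network input stays
#' 64 x 64.
#'
#' @param proj A [projection_set()].
#' @param row_range Length-2 inclusive range of detector rows to keep.
#' @return A [projection_set()] with rows outside the range zeroed; applying
#'   the same crop twice is a no-op.
#' @export
crop_projections <- function(proj, row_range) {
  rows <- proj$geometry$detector_rows
  row_range <- as.integer(row_range)
  if (length(row_range) != 2L || row_range[1] > row_range[2] ||
      row_range[1] < 1L || row_range[2] > rows) {
    abort_param("`row_range` must be a nonempty range within detector rows")
  }
  zero <- setdiff(seq_len(rows), seq(row_range[1], row_range[2]))
  out <- proj
  if (!is.null(out$counts)) out$counts[, zero, ] <- 0L
  if (!is.null(out$expected)) out$expected[, zero, ] <- 0
  out$provenance <- c(out$provenance, list(crop_rows = row_range))
  out
}

#' Thin an explicit event list (demonstration adapter)
#'
#' Explodes binned counts into individual events, applies per-event Bernoulli
#' selection, and re-bins — the literal list-mode procedure that
#' [binomial_thin()] reproduces distributionally without materialising the
#' event table. Intended for demonstrating the equivalence on small inputs.
#'
#' @inheritParams binomial_thin
#' @return A list of class `thin_result`, as [binomial_thin()].
#' @export
thin_events <- function(proj, p, seed = 1L) {
  assert_scalar_prob(p, "p")
  if (is.null(proj$counts)) abort_param("`proj` has no counts to thin")
  n <- as.vector(proj$counts)
  events <- rep(seq_along(n), n) # one row per detected photon: its bin id
  keep <- with_seed(seed, stats::runif(length(events)) < p)
  kept <- tabulate(events[keep], nbins = length(n))
  kept <- array(as.integer(kept), dim = dim(proj$counts))
  res <- binomial_thin(proj, p, seed) # for structure; overwrite draws
  res$kept$counts <- kept
  res$rejected$counts <- proj$counts - kept
  res
}
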