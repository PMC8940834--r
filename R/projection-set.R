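#' Construct a projection set
#'
#' The container for projection-space SPECT data: an optional integer count
#' grid and/or the noiseless expected means, both on a
#' `[n_views, rows, cols]` grid, plus the acquisition geometry and dose /
#' gating metadata.
#'
#' @param counts Integer array `[n_views, rows, cols]` of detected counts, or
#'   `NULL` if only expectations are available.
#' @param expected Optional nonnegative array of noiseless means, same shape.
#' @param geometry An [acquisition_geometry()].
#' @param dose_fraction Fraction of the standard dose retained, in `(0, 1]`.
#' @param gate Optional gate index (0-based) for gated data.
#' @param n_gates Optional total number of gates.
#' @param provenance Free-form list recording seeds and parent objects.
#' @return An object of class `projection_set`.
#' @export
projection_set <- function(counts = NULL, expected = NULL, geometry,
                           dose_fraction = 1, gate = NULL, n_gates = NULL,
                           provenance = list()) {
  if (is.null(counts) && is.null(expected)) {
    abort_param("a projection_set needs `counts` and/or `expected`")
  }
  shape <- c(geometry$n_views, geometry$detector_rows, geometry$detector_cols)
  for (arr in list(counts, expected)) {
    if (!is.null(arr)) {
      if (!identical(dim(arr), as.integer(shape))) {
        abort_param(sprintf(
          "projection grid is %s but geometry requires %s",
          paste(dim(arr), collapse = "x"), paste(shape, collapse = "x")))
      }
      if (any(arr < 0)) abort_param("projection values must be nonnegative")
    }
  }
  if (!is.null(counts) && any(counts != round(counts))) {
    abort_param("`counts` must be integers")
  }
  if (dose_fraction <= 0 || dose_fraction > 1) {
    abort_param("`dose_fraction` must be in (0, 1]")
  }
  structure(
    list(counts = counts, expected = expected, geometry = geometry,
         dose_fraction = dose_fraction, gate = gate, n_gates = n_gates,
         provenance = provenance),
    class = "projection_set"
  )
}

#' @export
print.projection_set <- function(x, ...) {
  what <- c(if (!is.null(x$counts)) "counts", if (!is.null(x$expected)) "expected")
  cat(sprintf(
    "<projection_set> %d views x %d x %d [%s], dose fraction %g%s\n",
    x$geometry$n_views, x$geometry$detector_rows, x$geometry$detector_cols,
    paste(what, collapse = " + "), x$dose_fraction,
    if (!is.null(x$gate)) sprintf(", gate %d/%d", x$gate, x$n_gates) else ""))
  if (!is.null(x$counts)) cat(sprintf("  total counts: %s\n",
                                      format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' Summarise a projection set as a tibble
#'
#' One row per view with total and peak counts, handy for quick inspection
#' and plotting of count statistics across the acquisition arc.
#'
#' @param x A [projection_set()].
#' @param ... Unused.
#' @return A tibble with columns `view`, `angle_deg`, `total`, `peak`.
#' @method tidy projection_set
#' @export
tidy.projection_set <- function(x, ...) {
  arr <- x$counts %||% x$expected
  tibble::tibble(
    view = seq_len(x$geometry$n_views),
    angle_deg = view_angles(x$geometry),
    total = apply(arr, 1L, sum),
    peak = apply(arr, 1L, max)
  )
}

#' Plot projection views
#'
#' Raster display of selected views of a projection set, in acquisition
#' (detector) coordinates.
#'
#' @param x A [projection_set()].
#' @param views Integer vector of view indices to display.
#' @param which `"counts"` or `"expected"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_views <- function(x, views = c(1L, 9L, 17L, 25L), which = "counts", ...) {
  arr <- if (which == "counts") x$counts else x$expected
  if (is.null(arr)) abort_param(sprintf("projection set has no %s grid", which))
  views <- views[views <= x$geometry$n_views]
  df <- purrr::map_dfr(views, function(v) {
    m <- arr[v, , ]
    tibble::tibble(
      view = sprintf("view %d (%.1f deg)", v, view_angles(x$geometry)[v]),
      row = rep(seq_len(nrow(m)), times = ncol(m)),
      col = rep(seq_len(ncol(m)), each = nrow(m)),
      value = as.vector(m))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = which) +
    ggplot2::facet_wrap(~view) +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}
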