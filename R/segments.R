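#' Simplified 17-segment summed perfusion score
#'
#' A transparent surrogate for commercial quantitative-perfusion software:
#' the short-axis volume is sampled on a 17-segment polar model (apex cap,
#' four apical sectors, six mid and six basal sectors) by taking, for every
#' slice and angular bin, the maximum value along the radial ray from the LV
#' axis (the standard maximal-count circumferential profile). Segment uptake
#' is the mean of its ray maxima as a fraction of the maximal profile value,
#' and is scored on the conventional 5-point scale: uptake >= 70% of maximum
#' scores 0, 50-69% scores 1, 30-49% scores 2, 10-29% scores 3 and < 10%
#' scores 4. The summed score is the total over the 17 segments.
#'
#' Angles are measured in the same convention as [lv_defect()] for a volume
#' whose long axis is +z with the apex towards low z, so defects carved into
#' a phantom land in the matching segments.
#'
#' @param volume A [recon_volume()] in SA orientation, or a 3D array with
#'   the LV long axis along z (apex at low z).
#' @param center Length-2 voxel coordinates of the LV axis in-plane
#'   (default the volume center).
#' @param axial_range Length-2 slice range `c(z_apex, z_base)`; if `NULL`,
#'   detected as the slices whose maximal profile value exceeds 30% of the
#'   global maximum.
#' @param n_angle_bins Angular sampling density (default 72 rays per slice).
#' @param ring_breaks Axial fractions (apex = 0, base = 1) separating the
#'   apex cap, apical, mid and basal rings.
#' @return An object of class `segment_scores`: a list with `segments` (a
#'   tibble with `segment`, `ring`, `uptake`, `score`) and `summed_score`.
#' @examples
#' ph <- make_phantom()
#' seg <- segment_scores(ph$activity, axial_range = c(18, 42))
#' seg$summed_score
#' @export
segment_scores <- function(volume, center = NULL, axial_range = NULL,
                           n_angle_bins = 72L,
                           ring_breaks = c(0.12, 0.413, 0.707)) {
  vals <- if (inherits(volume, "recon_volume")) volume$values else volume
  d <- dim(vals)
  center <- center %||% c((d[1] + 1) / 2, (d[2] + 1) / 2)

  # Maximal-count circumferential profiles restricted to the myocardial
  # annulus of each slice. The annulus is estimated per slice as the radial
  # band spanned by voxels above 30% of the slice maximum; angular bins with
  # no voxel inside the band (geometric sampling gaps on a coarse ring) are
  # marked missing rather than scored as absent uptake, while defect voxels
  # sit inside the band and correctly pull their ray towards zero.
  ix <- rep(seq_len(d[1]), d[2])
  iy <- rep(seq_len(d[2]), each = d[1])
  dx <- (ix - center[1])
  dy <- (iy - center[2])
  # same angular convention as the defect model: basis e1 = (0,-1,0),
  # e2 = (1,0,0) for a +z long axis
  ang <- (atan2(dx, -dy) * 180 / pi) %% 360
  bin <- pmin(floor(ang / (360 / n_angle_bins)) + 1L, n_angle_bins)
  rad <- sqrt(dx^2 + dy^2)
  prof <- sapply(seq_len(d[3]), function(z) {
    slice <- as.vector(vals[, , z])
    out <- rep(NA_real_, n_angle_bins)
    smax <- max(slice)
    if (smax <= 0) return(out)
    rsel <- rad[slice >= 0.3 * smax]
    inband <- rad >= min(rsel) - 1e-9 & rad <= max(rsel) + 1e-9
    agg <- tapply(slice[inband], bin[inband], max)
    out[as.integer(names(agg))] <- agg
    out
  }) # n_angle_bins x nz

  slice_max <- apply(prof, 2, function(col) {
    if (all(is.na(col))) 0 else max(col, na.rm = TRUE)
  })
  if (is.null(axial_range)) {
    keep <- which(slice_max > 0.3 * max(slice_max))
    if (!length(keep)) abort_param("no myocardial slices detected")
    axial_range <- range(keep)
  }
  zs <- seq(axial_range[1], axial_range[2])
  if (length(zs) < 4L) abort_param("axial range too short for 4 rings")
  tfrac <- (zs - axial_range[1]) / (axial_range[2] - axial_range[1])
  ring_of <- cut(tfrac, breaks = c(-Inf, ring_breaks, Inf),
                 labels = c("apex", "apical", "mid", "basal"))

  ray_tbl <- tidyr::expand_grid(z = zs, bin = seq_len(n_angle_bins))
  ray_tbl$ring <- rep(as.character(ring_of), each = n_angle_bins)
  ray_tbl$angle <- (ray_tbl$bin - 0.5) * 360 / n_angle_bins
  ray_tbl$value <- prof[cbind(ray_tbl$bin, ray_tbl$z)]
  ray_tbl <- ray_tbl[!is.na(ray_tbl$value), ]

  ray_tbl$segment <- segment_index(ray_tbl$ring, ray_tbl$angle)
  up <- tapply(ray_tbl$value, ray_tbl$segment, mean)
  uptake <- rep(NA_real_, 17L)
  uptake[as.integer(names(up))] <- up
  peak <- max(ray_tbl$value)
  if (peak <= 0) abort_param("myocardial profile is empty")
  uptake <- uptake / peak

  score <- score_uptake(uptake)
  rings <- c(rep("basal", 6), rep("mid", 6), rep("apical", 4), "apex")
  structure(
    list(segments = tibble::tibble(segment = 1:17, ring = rings,
                                   uptake = uptake, score = score),
         summed_score = sum(score, na.rm = TRUE)),
    class = "segment_scores"
  )
}

# AHA-style numbering: basal ring 1-6, mid 7-12 (60-degree sectors),
# apical 13-16 (90-degree sectors), apex cap 17.
segment_index <- function(ring, angle) {
  sector6 <- pmin(floor(angle / 60) + 1L, 6L)
  sector4 <- pmin(floor(angle / 90) + 1L, 4L)
  ifelse(ring == "basal", sector6,
         ifelse(ring == "mid", 6L + sector6,
                ifelse(ring == "apical", 12L + sector4, 17L)))
}

#' Score relative uptake on the 5-point perfusion scale
#'
#' @param uptake Uptake as a fraction of maximal uptake, in `[0, 1]`.
#' @return Integer scores 0 (normal) to 4 (absent uptake); `NA` passes
#'   through.
#' @export
score_uptake <- function(uptake) {
  s <- ifelse(uptake >= 0.70, 0L,
              ifelse(uptake >= 0.50, 1L,
                     ifelse(uptake >= 0.30, 2L,
                            ifelse(uptake >= 0.10, 3L, 4L))))
  as.integer(s)
}

#' @export
print.segment_scores <- function(x, ...) {
  cat(sprintf("<segment_scores> summed score %d\n", x$summed_score))
  print(x$segments, n = 17)
  invisible(x)
}

#' @method tidy segment_scores
#' @param x A [segment_scores()] object.
#' @param ... Unused.
#' @return The per-segment tibble.
#' @rdname segment_scores
#' @export
tidy.segment_scores <- function(x, ...) x$segments
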