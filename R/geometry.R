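#' Acquisition geometry for a cardiac SPECT camera
#'
#' Describes the projection sampling of a dual-head 90-degree cardiac camera:
#' parallel-beam views evenly spaced over a limited arc (by default 32 views
#' over 180 degrees, right anterior oblique to left posterior oblique) onto a
#' 64 x 64 detector with 6.4 mm pixels.
#'
#' @param n_views Number of projection views (default 32).
#' @param arc_deg Angular arc covered by the views, in degrees (default 180).
#' @param start_deg Angle of the first view in degrees; 0 points along +x of
#'   the transaxial plane, angles increase counter-clockwise. The default -45
#'   corresponds to a right-anterior-oblique start.
#' @param detector_rows,detector_cols Detector matrix size (default 64 x 64).
#' @param pixel_mm Detector pixel size in mm (default 6.4).
#' @return An object of class `acquisition_geometry`.
#' @examples
#' geom <- acquisition_geometry()
#' view_angles(geom)[1:4]
#' @export
acquisition_geometry <- function(n_views = 32L, arc_deg = 180, start_deg = -45,
                                 detector_rows = 64L, detector_cols = 64L,
                                 pixel_mm = 6.4) {
  if (n_views < 1L) abort_param("`n_views` must be >= 1")
  structure(
    list(n_views = as.integer(n_views), arc_deg = arc_deg,
         start_deg = start_deg, detector_rows = as.integer(detector_rows),
         detector_cols = as.integer(detector_cols), pixel_mm = pixel_mm),
    class = "acquisition_geometry"
  )
}

#' @export
print.acquisition_geometry <- function(x, ...) {
  cat(sprintf(
    "<acquisition_geometry> %d views over %g deg (start %g deg), %d x %d detector, %g mm pixels\n",
    x$n_views, x$arc_deg, x$start_deg, x$detector_rows, x$detector_cols,
    x$pixel_mm))
  invisible(x)
}

#' View angles of a geometry
#'
#' Evenly spaced angles over the acquisition arc. The step is `arc_deg /
#' n_views` (the arc end is excluded, as on a camera that stops short of a
#' full half-turn revisit).
#'
#' @param geometry An [acquisition_geometry()].
#' @return Numeric vector of view angles in degrees.
#' @export
view_angles <- function(geometry) {
  geometry$start_deg +
    (seq_len(geometry$n_views) - 1L) * geometry$arc_deg / geometry$n_views
}

# ---------------------------------------------------------------------------
# Parallel-beam system matrices.
#
# For view angle theta the detector transverse coordinate is s along
# e_s = (cos t, sin t) and the integration direction is e_t = (-sin t, cos t).
# Each (s, t) sample point is bilinearly interpolated from the transaxial
# grid; rows of the per-view operator sum over t, so A_theta maps a
# vectorised in-plane slice (nx * ny) to an s-profile (length ns). The
# detector axial axis coincides with the volume z axis, so a full view is
# A_theta %*% matrix(volume, nx * ny, nz). The OSEM backprojector is the
# exact transpose t(A_theta).
# ---------------------------------------------------------------------------

view_operator <- function(theta_deg, nx, ny, ns, nt = max(nx, ny)) {
  th <- theta_deg * pi / 180
  es <- c(cos(th), sin(th))
  et <- c(-sin(th), cos(th))
  cx <- (nx + 1) / 2
  cy <- (ny + 1) / 2
  cs <- (ns + 1) / 2
  ct <- (nt + 1) / 2

  grid <- expand.grid(s = seq_len(ns), t = seq_len(nt))
  px <- cx + (grid$s - cs) * es[1] + (grid$t - ct) * et[1]
  py <- cy + (grid$s - cs) * es[2] + (grid$t - ct) * et[2]

  x0 <- floor(px); y0 <- floor(py)
  fx <- px - x0;   fy <- py - y0

  rows <- rep(grid$s, 4L)
  xs <- c(x0, x0 + 1, x0, x0 + 1)
  ys <- c(y0, y0, y0 + 1, y0 + 1)
  ws <- c((1 - fx) * (1 - fy), fx * (1 - fy), (1 - fx) * fy, fx * fy)

  keep <- xs >= 1 & xs <= nx & ys >= 1 & ys <= ny & ws > 0
  Matrix::sparseMatrix(
    i = rows[keep],
    j = xs[keep] + (ys[keep] - 1L) * nx,
    x = ws[keep],
    dims = c(ns, nx * ny)
  )
}

# Cache of per-geometry operator lists (building 32 sparse matrices takes a
# noticeable fraction of a second; OSEM reuses them every subset pass).
.projector_cache <- new.env(parent = emptyenv())

view_operators <- function(geometry, nx, ny) {
  key <- paste(nx, ny, geometry$n_views, geometry$arc_deg, geometry$start_deg,
               geometry$detector_cols, sep = "|")
  hit <- .projector_cache[[key]]
  if (!is.null(hit)) return(hit)
  ops <- lapply(view_angles(geometry), view_operator,
                nx = nx, ny = ny, ns = geometry$detector_cols)
  .projector_cache[[key]] <- ops
  ops
}
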