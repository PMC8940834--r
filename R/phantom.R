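#' Parameters of the left-ventricle shell
#'
#' Geometry of the myocardial activity model: a half-ellipsoidal shell
#' (an ellipsoidal shell truncated at the base plane, open towards the
#' valve plane) with uniform tracer uptake.
#'
#' @param center Voxel coordinates (length 3) of the LV center; default the
#'   grid center.
#' @param axis Long-axis direction as a length-3 vector (apex at the negative
#'   end); normalised internally. Default `c(0, 0, 1)`.
#' @param semi_axes_mm Outer semi-axes `(a, b, c)` of the ellipsoid in mm,
#'   `c` along the long axis.
#' @param wall_mm Myocardial wall thickness in mm (must be smaller than every
#'   outer semi-axis).
#' @param base_cut Position of the base plane as a fraction of `c` along the
#'   long axis from the LV center (default 0.3); voxels beyond it are removed.
#' @return A list of class `lv_params`.
#' @export
lv_parameters <- function(center = NULL, axis = c(0, 0, 1),
                          semi_axes_mm = c(32, 32, 48), wall_mm = 10,
                          base_cut = 0.3) {
  if (wall_mm >= min(semi_axes_mm)) {
    abort_param("`wall_mm` must be smaller than every outer semi-axis")
  }
  n <- sqrt(sum(axis^2))
  if (n == 0) abort_param("`axis` must be a nonzero vector")
  structure(list(center = center, axis = axis / n,
                 semi_axes_mm = semi_axes_mm, wall_mm = wall_mm,
                 base_cut = base_cut),
            class = "lv_params")
}

#' Describe a perfusion defect
#'
#' A defect occupies an angular sector around the LV long axis and an axial
#' band, and scales the shell activity there by `1 - severity`.
#'
#' @param angle_deg Length-2 angular span in degrees, counter-clockwise from
#'   the first transverse basis axis; may wrap past 360 (e.g. `c(300, 30)`).
#' @param axial Length-2 span as fractions of the apex-to-base extent
#'   (0 = apex, 1 = base).
#' @param severity Fractional activity reduction in `[0, 1]`; 1 means a
#'   complete perfusion defect.
#' @return A list of class `lv_defect`.
#' @export
lv_defect <- function(angle_deg = c(0, 60), axial = c(0.2, 0.7),
                      severity = 0.5) {
  assert_scalar_prob(severity, "severity")
  if (any(axial < 0) || any(axial > 1) || axial[1] >= axial[2]) {
    abort_param("`axial` must be an increasing span within [0, 1]")
  }
  structure(list(angle_deg = angle_deg, axial = axial, severity = severity),
            class = "lv_defect")
}

# Orthonormal basis (e1, e2, e3 = axis); defect angles are measured from e1.
axis_basis <- function(axis) {
  ref <- if (abs(axis[3]) > 0.9) c(1, 0, 0) else c(0, 0, 1)
  e1 <- pracma_cross(ref, axis)
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- pracma_cross(axis, e1)
  rbind(e1, e2, axis)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Generate a synthetic cardiac activity phantom
#'
#' Builds a 3D relative-activity map containing a uniform half-ellipsoidal
#' LV myocardial shell, optional perfusion defects (each defect multiplies
#' the shell activity by `1 - severity` within its angular/axial span) and an
#' optional extra-cardiac hot blob emulating liver uptake. The ground-truth
#' shell and defect masks are stored with the phantom.
#'
#' @param lv [lv_parameters()] describing the shell.
#' @param defects List of [lv_defect()] objects (default none).
#' @param grid_size Cubic grid side in voxels (default 64, minimum 16).
#' @param voxel_mm Isotropic voxel size in mm (default 6.4).
#' @param shell_activity Relative activity of the healthy shell (default 1).
#' @param liver Optional list `(center, semi_axes_mm, activity)` adding a
#'   uniform ellipsoidal hot blob.
#' @param seed Integer recorded with the phantom (the construction itself is
#'   deterministic; the seed names the phantom for downstream substreams).
#' @return An object of class `phantom` with fields `activity` (3D array),
#'   `voxel_mm`, `lv_params`, `defects`, `seed` and `masks` (logical arrays
#'   `shell`, `defect`, plus one mask per defect).
#' @examples
#' ph <- make_phantom(defects = list(lv_defect(severity = 1)))
#' sum(ph$masks$defect)
#' @export
make_phantom <- function(lv = lv_parameters(), defects = list(),
                         grid_size = 64L, voxel_mm = 6.4,
                         shell_activity = 1, liver = NULL, seed = 1L) {
  if (grid_size < 16L) abort_param("`grid_size` must be at least 16")
  n <- as.integer(grid_size)
  center <- lv$center %||% rep((n + 1) / 2, 3)

  idx <- seq_len(n)
  co <- (idx - 1) + 1 # voxel index grid (1-based)
  gx <- rep(co, times = n * n)
  gy <- rep(rep(co, each = n), times = n)
  gz <- rep(co, each = n * n)
  # mm offsets from the LV center
  dx <- (gx - center[1]) * voxel_mm
  dy <- (gy - center[2]) * voxel_mm
  dz <- (gz - center[3]) * voxel_mm

  B <- axis_basis(lv$axis)
  v1 <- dx * B[1, 1] + dy * B[1, 2] + dz * B[1, 3]
  v2 <- dx * B[2, 1] + dy * B[2, 2] + dz * B[2, 3]
  u  <- dx * B[3, 1] + dy * B[3, 2] + dz * B[3, 3]

  a <- lv$semi_axes_mm[1]; b <- lv$semi_axes_mm[2]; cc <- lv$semi_axes_mm[3]
  inner <- pmax(lv$semi_axes_mm - lv$wall_mm, 1e-6)
  q_out <- (v1 / a)^2 + (v2 / b)^2 + (u / cc)^2
  q_in  <- (v1 / inner[1])^2 + (v2 / inner[2])^2 + (u / inner[3])^2
  base_mm <- lv$base_cut * cc
  shell <- q_out <= 1 & q_in > 1 & u <= base_mm
  if (!any(shell)) abort_param("LV shell is empty; check geometry")

  activity <- rep(0, n^3)
  activity[shell] <- shell_activity

  # angular/axial coordinates for defect carving
  ang <- (atan2(v2, v1) * 180 / pi) %% 360
  axial_frac <- (u + cc) / (base_mm + cc)

  defect_masks <- list()
  combined <- rep(FALSE, n^3)
  for (k in seq_along(defects)) {
    d <- defects[[k]]
    a0 <- d$angle_deg[1] %% 360
    a1 <- d$angle_deg[2] %% 360
    in_angle <- if (a0 <= a1) ang >= a0 & ang < a1 else ang >= a0 | ang < a1
    m <- shell & in_angle & axial_frac >= d$axial[1] & axial_frac <= d$axial[2]
    activity[m] <- activity[m] * (1 - d$severity)
    defect_masks[[k]] <- array(m, dim = c(n, n, n))
    combined <- combined | m
  }

  if (!is.null(liver)) {
    lc <- liver$center
    ls <- liver$semi_axes_mm
    ql <- ((gx - lc[1]) * voxel_mm / ls[1])^2 +
          ((gy - lc[2]) * voxel_mm / ls[2])^2 +
          ((gz - lc[3]) * voxel_mm / ls[3])^2
    activity[ql <= 1] <- activity[ql <= 1] + (liver$activity %||% 1.5)
  }

  structure(
    list(activity = array(activity, dim = c(n, n, n)), voxel_mm = voxel_mm,
         lv_params = lv, defects = defects, seed = as.integer(seed),
         masks = c(list(shell = array(shell, dim = c(n, n, n)),
                        defect = array(combined, dim = c(n, n, n))),
                   stats::setNames(defect_masks,
                                   if (length(defect_masks))
                                     paste0("defect_", seq_along(defect_masks))
                                   else character()))),
    class = "phantom"
  )
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf(
    "<phantom> %s grid, %g mm voxels, %d shell voxels, %d defect(s)\n",
    paste(dim(x$activity), collapse = "x"), x$voxel_mm,
    sum(x$masks$shell), length(x$defects)))
  invisible(x)
}

#' Forward-project a phantom
#'
#' Parallel-beam line integrals of the activity map along each view of the
#' acquisition arc (rotate-and-sum with bilinear interpolation). No
#' attenuation, scatter or depth-dependent resolution is modelled. The
#' result carries only the noiseless `expected` grid, in units of
#' activity x mm; counts are attached later by [sample_counts()].
#'
#' @param phantom A [make_phantom()] object.
#' @param geometry An [acquisition_geometry()]; pixel size must match the
#'   phantom voxel size and detector rows must match the grid z extent.
#' @return A [projection_set()] with `expected` set and `counts` unset.
#' @export
project <- function(phantom, geometry = acquisition_geometry()) {
  d <- dim(phantom$activity)
  if (abs(geometry$pixel_mm - phantom$voxel_mm) > 1e-9) {
    abort_param("detector pixel size must match phantom voxel size")
  }
  if (geometry$detector_rows != d[3]) {
    abort_param("detector rows must match the phantom z extent")
  }
  ops <- view_operators(geometry, d[1], d[2])
  Vmat <- matrix(phantom$activity, d[1] * d[2], d[3])
  expected <- array(0, dim = c(geometry$n_views, geometry$detector_rows,
                               geometry$detector_cols))
  for (v in seq_len(geometry$n_views)) {
    m <- as.matrix(ops[[v]] %*% Vmat) * phantom$voxel_mm # ns x nz
    expected[v, , ] <- t(m)
  }
  expected[expected < 0] <- 0
  projection_set(expected = expected, geometry = geometry,
                 provenance = list(phantom_seed = phantom$seed))
}

#' Draw Poisson counts for a projection set
#'
#' Rescales the noiseless expectation so that its grand total equals
#' `total_counts`, then draws each bin independently from a Poisson law with
#' that mean — the emission counting model of a SPECT acquisition at a chosen
#' standard-dose count level.
#'
#' @param proj A [projection_set()] with `expected` set.
#' @param total_counts Target expected total counts over all views
#'   (default 2e5, the package's standard-dose level for a non-gated study).
#' @param seed Integer seed; fixed seed gives bit-identical counts.
#' @return A [projection_set()] with integer `counts` and the rescaled
#'   `expected` grid.
#' @export
sample_counts <- function(proj, total_counts = 2e5, seed = 1L) {
  if (is.null(proj$expected)) abort_param("`proj` has no expected grid")
  if (total_counts <= 0) abort_param("`total_counts` must be positive")
  tot <- sum(proj$expected)
  if (tot <= 0) abort_param("expected grid is all zero; nothing to sample")
  lambda <- proj$expected * (total_counts / tot)
  counts <- with_seed(seed, stats::rpois(length(lambda), lambda))
  projection_set(
    counts = array(as.integer(counts), dim = dim(lambda)),
    expected = lambda, geometry = proj$geometry,
    dose_fraction = proj$dose_fraction,
    gate = proj$gate, n_gates = proj$n_gates,
    provenance = c(proj$provenance, list(poisson_seed = as.integer(seed)))
  )
}
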