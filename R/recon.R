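#' Reconstructed volume container
#'
#' @param values Nonnegative 3D array of reconstructed activity.
#' @param voxel_mm Isotropic voxel size in mm.
#' @param orientation One of `"transaxial"`, `"SA"`, `"VLA"`, `"HLA"`.
#' @param recon_params List recording reconstruction settings.
#' @return An object of class `recon_volume`.
#' @export
recon_volume <- function(values, voxel_mm = 6.4, orientation = "transaxial",
                         recon_params = list()) {
  orientation <- match.arg(orientation, c("transaxial", "SA", "VLA", "HLA"))
  if (any(values < 0)) abort_param("reconstructed values must be nonnegative")
  structure(list(values = values, voxel_mm = voxel_mm,
                 orientation = orientation, recon_params = recon_params),
            class = "recon_volume")
}

#' @export
print.recon_volume <- function(x, ...) {
  cat(sprintf("<recon_volume> %s, %s, %g mm voxels\n",
              paste(dim(x$values), collapse = "x"), x$orientation,
              x$voxel_mm))
  invisible(x)
}

#' Ordered-subsets expectation maximization reconstruction
#'
#' Iterative Poisson-likelihood reconstruction with multiplicative EM updates
#' over interleaved view subsets (even/odd view partition for 2 subsets).
#' The back-projector is the exact transpose of the forward projector used
#' by [project()], so with `n_subsets = 1` (MLEM) the Poisson log-likelihood
#' of the data is non-decreasing across iterations. Voxels with zero
#' sensitivity are frozen at zero rather than divided by zero. The default
#' 8 iterations with 2 subsets matches routine cardiac practice.
#'
#' @param proj A [projection_set()] with `counts` set (expectations are also
#'   accepted for noiseless studies).
#' @param n_iterations Number of full passes over all subsets (default 8).
#' @param n_subsets Number of interleaved view subsets (default 2); must
#'   divide the number of views.
#' @param init Optional strictly positive initial volume (default uniform
#'   ones).
#' @return A [recon_volume()] in transaxial orientation.
#' @export
osem <- function(proj, n_iterations = 8L, n_subsets = 2L, init = NULL) {
  geom <- proj$geometry
  data <- proj$counts %||% proj$expected
  if (is.null(data)) abort_param("`proj` carries no data")
  if (geom$n_views %% n_subsets != 0L || n_subsets < 1L) {
    abort_param("`n_subsets` must divide the number of views")
  }
  nx <- geom$detector_cols; ny <- geom$detector_cols; nz <- geom$detector_rows
  vox <- geom$pixel_mm
  ops <- view_operators(geom, nx, ny)

  X <- if (is.null(init)) matrix(1, nx * ny, nz) else {
    if (any(init <= 0)) abort_param("`init` must be strictly positive")
    matrix(init, nx * ny, nz)
  }
  subsets <- split(seq_len(geom$n_views),
                   (seq_len(geom$n_views) - 1L) %% n_subsets)
  # per-subset sensitivity (same for every z slice)
  sens <- lapply(subsets, function(vs) {
    s <- Reduce(`+`, lapply(ops[vs], Matrix::colSums)) * vox
    as.numeric(s)
  })
  y_views <- lapply(seq_len(geom$n_views), function(v) t(data[v, , ])) # ns x nz

  for (it in seq_len(n_iterations)) {
    for (k in seq_along(subsets)) {
      vs <- subsets[[k]]
      back <- matrix(0, nx * ny, nz)
      for (v in vs) {
        fp <- as.matrix(ops[[v]] %*% X) * vox
        ratio <- y_views[[v]]
        nz_fp <- fp > 0
        ratio[nz_fp] <- ratio[nz_fp] / fp[nz_fp]
        ratio[!nz_fp] <- 0
        back <- back + as.matrix(Matrix::crossprod(ops[[v]], ratio)) * vox
      }
      s <- sens[[k]]
      ok <- s > 0
      X[ok, ] <- X[ok, ] * back[ok, ] / s[ok]
      X[!ok, ] <- 0
    }
  }
  recon_volume(array(X, dim = c(nx, ny, nz)), voxel_mm = vox,
               orientation = "transaxial",
               recon_params = list(n_iterations = n_iterations,
                                   n_subsets = n_subsets,
                                   algorithm = "OSEM"))
}

#' Poisson log-likelihood of projection data under a volume
#'
#' `sum(y * log(Ax) - Ax)` over all views (terms with `Ax = 0, y = 0`
#' contribute 0; `Ax = 0, y > 0` gives `-Inf`). Used to verify EM
#' monotonicity of MLEM.
#'
#' @param proj A [projection_set()] with counts.
#' @param volume A [recon_volume()] or 3D array.
#' @return A single number.
#' @export
poisson_loglik <- function(proj, volume) {
  geom <- proj$geometry
  vals <- if (inherits(volume, "recon_volume")) volume$values else volume
  d <- dim(vals)
  ops <- view_operators(geom, d[1], d[2])
  Xm <- matrix(vals, d[1] * d[2], d[3])
  ll <- 0
  for (v in seq_len(geom$n_views)) {
    fp <- as.matrix(ops[[v]] %*% Xm) * geom$pixel_mm
    y <- t(proj$counts[v, , ])
    pos <- fp > 0
    ll <- ll + sum(y[pos] * log(fp[pos])) - sum(fp)
    if (any(y[!pos] > 0)) return(-Inf)
  }
  ll
}

#' Butterworth transfer function
#'
#' Squared-magnitude low-pass gain `1 / (1 + (f / cutoff)^(2 * order))` at a
#' normalised frequency `f` expressed as a fraction of the Nyquist frequency,
#' the dominant convention in nuclear-medicine post-filtering (so the gain at
#' the cutoff itself is exactly 0.5).
#'
#' @param f_norm Frequency as a fraction of Nyquist (0 = DC, 1 = Nyquist).
#' @param order Filter order (>= 1; default 10).
#' @param cutoff Cutoff as a fraction of Nyquist, in `(0, 1]` (default 0.45).
#' @return Gain values in `(0, 1]`.
#' @export
butterworth_gain <- function(f_norm, order = 10, cutoff = 0.45) {
  if (order < 1) abort_param("`order` must be >= 1")
  if (cutoff <= 0 || cutoff > 1) abort_param("`cutoff` must be in (0, 1]")
  1 / (1 + (f_norm / cutoff)^(2 * order))
}

fft_freqs <- function(n) {
  (((seq_len(n) - 1L) + floor(n / 2)) %% n - floor(n / 2)) / n
}

#' Butterworth post-smoothing filter
#'
#' Radially symmetric frequency-domain low-pass filtering of a 2D or 3D
#' grid: multiply the FFT by [butterworth_gain()] of the radial frequency
#' and invert. The DC component (image mean) is preserved exactly and the
#' output is real.
#'
#' @param x A [recon_volume()], 3D array or 2D matrix.
#' @inheritParams butterworth_gain
#' @return Same type as the input, filtered.
#' @export
butterworth <- function(x, order = 10, cutoff = 0.45) {
  if (inherits(x, "recon_volume")) {
    out <- x
    v <- butterworth(x$values, order, cutoff)
    v[v < 0] <- 0 # ringing can dip slightly below zero; volumes stay nonneg
    out$values <- v
    out$recon_params$filter <- list(type = "butterworth", order = order,
                                    cutoff = cutoff)
    return(out)
  }
  d <- dim(x) %||% length(x)
  freqs <- lapply(d, fft_freqs)
  grids <- do.call(expand.grid, freqs)
  r2 <- Reduce(`+`, lapply(grids, function(f) f^2))
  f_norm <- sqrt(r2) / 0.5
  H <- array(butterworth_gain(f_norm, order, cutoff), dim = d)
  Re(stats::fft(stats::fft(x) * H, inverse = TRUE)) / prod(d)
}

# Trilinear (or nearest) sampling of `vals` at fractional voxel coordinates.
interp3 <- function(vals, px, py, pz, method = "linear") {
  d <- dim(vals)
  if (method == "nearest") {
    xi <- round(px); yi <- round(py); zi <- round(pz)
    ok <- xi >= 1 & xi <= d[1] & yi >= 1 & yi <= d[2] & zi >= 1 & zi <= d[3]
    out <- numeric(length(px))
    out[ok] <- vals[cbind(xi[ok], yi[ok], zi[ok])]
    return(out)
  }
  x0 <- floor(px); y0 <- floor(py); z0 <- floor(pz)
  fx <- px - x0;   fy <- py - y0;   fz <- pz - z0
  out <- numeric(length(px))
  for (k in 0:7) {
    ox <- k %% 2; oy <- (k %/% 2) %% 2; oz <- k %/% 4
    xi <- x0 + ox; yi <- y0 + oy; zi <- z0 + oz
    w <- (if (ox) fx else 1 - fx) * (if (oy) fy else 1 - fy) *
         (if (oz) fz else 1 - fz)
    ok <- w > 0 & xi >= 1 & xi <= d[1] & yi >= 1 & yi <= d[2] &
          zi >= 1 & zi <= d[3]
    if (any(ok)) out[ok] <- out[ok] + w[ok] * vals[cbind(xi[ok], yi[ok], zi[ok])]
  }
  out
}

rot_z <- function(deg) {
  t <- deg * pi / 180
  matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
}
rot_y <- function(deg) {
  t <- deg * pi / 180
  matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3, 3)
}

#' Rigid rotation of a volume
#'
#' Rotates a 3D array about its center: azimuth about the z axis followed by
#' elevation about the (rotated) y axis, sampling with trilinear (or
#' nearest-neighbour) interpolation. `rotate_volume(v, az, el, inverse =
#' TRUE)` applies the inverse rotation.
#'
#' @param vals 3D array.
#' @param azimuth_deg,elevation_deg Rotation angles in degrees.
#' @param method `"linear"` (default) or `"nearest"`.
#' @param inverse Apply the inverse rotation instead.
#' @return A rotated 3D array of the same shape.
#' @export
rotate_volume <- function(vals, azimuth_deg, elevation_deg = 0,
                          method = "linear", inverse = FALSE) {
  d <- dim(vals)
  M <- rot_z(azimuth_deg) %*% rot_y(elevation_deg)
  if (inverse) M <- t(M)
  ctr <- (d + 1) / 2
  g <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  P <- t(cbind(g$x - ctr[1], g$y - ctr[2], g$z - ctr[3]))
  S <- M %*% P
  out <- interp3(vals, S[1, ] + ctr[1], S[2, ] + ctr[2], S[3, ] + ctr[3],
                 method = method)
  array(out, dim = d)
}

#' Reorient a transaxial volume into cardiac short-axis
#'
#' Applies the rigid rotation that aligns the stated LV long axis (given by
#' its azimuth and elevation) with the volume z axis, yielding a short-axis
#' (SA) stack; vertical and horizontal long-axis stacks are axis-permuted
#' views of the SA volume, obtainable with [long_axis_stacks()].
#'
#' @param volume A [recon_volume()] in transaxial orientation.
#' @param azimuth_deg,elevation_deg LV long-axis orientation in degrees
#'   (0, 0 leaves the volume unchanged up to interpolation).
#' @param method Interpolation for resampling; `"linear"` or `"nearest"`.
#' @return A [recon_volume()] with orientation `"SA"`.
#' @export
reorient <- function(volume, azimuth_deg = 0, elevation_deg = 0,
                     method = "linear") {
  stopifnot(inherits(volume, "recon_volume"))
  v <- rotate_volume(volume$values, azimuth_deg, elevation_deg,
                     method = method)
  v[v < 0] <- 0
  recon_volume(v, voxel_mm = volume$voxel_mm, orientation = "SA",
               recon_params = c(volume$recon_params,
                                list(azimuth_deg = azimuth_deg,
                                     elevation_deg = elevation_deg)))
}

#' Long-axis slice stacks from a short-axis volume
#'
#' @param sa A [recon_volume()] with orientation `"SA"`.
#' @return A list with `VLA` and `HLA` [recon_volume()]s (axis permutations
#'   of the SA stack).
#' @export
long_axis_stacks <- function(sa) {
  stopifnot(inherits(sa, "recon_volume"), sa$orientation == "SA")
  list(
    VLA = recon_volume(aperm(sa$values, c(3, 2, 1)), sa$voxel_mm, "VLA",
                       sa$recon_params),
    HLA = recon_volume(aperm(sa$values, c(1, 3, 2)), sa$voxel_mm, "HLA",
                       sa$recon_params)
  )
}
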