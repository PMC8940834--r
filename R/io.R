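#' Write a projection set to an .sproj file
#'
#' The container is a plain-text header of `key: value` lines terminated by
#' a blank line, followed by the counts as little-endian 32-bit unsigned
#' integers in view-major order (row-major within each view). Integer counts
#' round-trip bit-exactly; real-valued grids (e.g. network predictions) are
#' stored as scaled integers with the scaling factor recorded in the header.
#'
#' @param proj A [projection_set()].
#' @param path Destination path (conventionally `.sproj`).
#' @param scaling Integer quantisation factor for real-valued grids
#'   (default 1 for counts, 1000 for expectation-only sets).
#' @return `path`, invisibly.
#' @export
write_sproj <- function(proj, path, scaling = NULL) {
  stopifnot(inherits(proj, "projection_set"))
  geom <- proj$geometry
  arr <- proj$counts
  if (is.null(arr)) {
    scaling <- scaling %||% 1000
    arr <- round(proj$expected * scaling)
  } else {
    scaling <- scaling %||% 1
    if (scaling != 1) arr <- round(arr * scaling)
  }
  hdr <- c(
    matrix_rows = geom$detector_rows, matrix_cols = geom$detector_cols,
    n_views = geom$n_views, pixel_mm = geom$pixel_mm,
    arc_deg = geom$arc_deg, start_deg = geom$start_deg,
    dose_fraction = proj$dose_fraction,
    gate = proj$gate, n_gates = proj$n_gates,
    seed = proj$provenance$poisson_seed, scaling = scaling
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(paste(names(hdr), unlist(hdr), sep = ": ",
                         collapse = "\n"), "\n\n"),
            con, eos = NULL)
  flat <- as.integer(aperm(arr, c(3, 2, 1)))
  if (any(flat < 0)) abort_param("negative values cannot be stored")
  writeBin(flat, con, size = 4L, endian = "little")
  invisible(path)
}

#' Read a projection set from an .sproj file
#'
#' @param path File written by [write_sproj()].
#' @return A [projection_set()]. Sets written with `scaling != 1` come back
#'   in the `expected` slot (de-quantised); `scaling == 1` restores integer
#'   counts bit-exactly.
#' @export
read_sproj <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  sep <- which(raw[-length(raw)] == as.raw(10L) & raw[-1L] == as.raw(10L))[1]
  if (is.na(sep)) abort_param("malformed .sproj: missing blank line after header")
  hdr_txt <- rawToChar(raw[seq_len(sep - 1L)])
  fields <- list()
  for (line in strsplit(hdr_txt, "\n", fixed = TRUE)[[1]]) {
    kv <- strsplit(line, ": ", fixed = TRUE)[[1]]
    if (length(kv) != 2L) {
      abort_param(sprintf("malformed .sproj header line: '%s'", line))
    }
    fields[[kv[1]]] <- as.numeric(kv[2])
  }
  need <- c("matrix_rows", "matrix_cols", "n_views", "pixel_mm", "scaling")
  for (k in need) {
    if (is.null(fields[[k]])) {
      abort_param(sprintf("malformed .sproj header: missing key '%s'", k))
    }
  }
  n_expect <- fields$n_views * fields$matrix_rows * fields$matrix_cols
  payload <- raw[(sep + 2L):length(raw)]
  if (length(payload) != 4L * n_expect) {
    abort_param(sprintf("truncated .sproj payload: expected %d bytes, found %d",
                        4L * n_expect, length(payload)))
  }
  flat <- readBin(payload, "integer", n_expect, size = 4L, endian = "little")
  arr <- aperm(array(flat, dim = c(fields$matrix_cols, fields$matrix_rows,
                                   fields$n_views)), c(3, 2, 1))
  geom <- acquisition_geometry(
    n_views = fields$n_views,
    arc_deg = fields$arc_deg %||% 180, start_deg = fields$start_deg %||% -45,
    detector_rows = fields$matrix_rows, detector_cols = fields$matrix_cols,
    pixel_mm = fields$pixel_mm)
  prov <- list()
  if (!is.null(fields$seed)) prov$poisson_seed <- as.integer(fields$seed)
  if (fields$scaling == 1) {
    projection_set(counts = arr, geometry = geom,
                   dose_fraction = fields$dose_fraction %||% 1,
                   gate = if (!is.null(fields$gate)) as.integer(fields$gate),
                   n_gates = if (!is.null(fields$n_gates)) as.integer(fields$n_gates),
                   provenance = prov)
  } else {
    projection_set(expected = arr / fields$scaling, geometry = geom,
                   dose_fraction = fields$dose_fraction %||% 1,
                   gate = if (!is.null(fields$gate)) as.integer(fields$gate),
                   n_gates = if (!is.null(fields$n_gates)) as.integer(fields$n_gates),
                   provenance = prov)
  }
}

#' Write a reconstructed volume as NIfTI-1
#'
#' Voxel size is stored in the NIfTI pixdim and the cardiac orientation tag
#' in the description field.
#'
#' @param volume A [recon_volume()].
#' @param path Destination (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "recon_volume"))
  img <- RNifti::asNifti(volume$values)
  RNifti::pixdim(img) <- rep(volume$voxel_mm, 3)
  img <- RNifti::asNifti(img, list(descrip = paste0("orientation=",
                                                    volume$orientation)))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a reconstructed volume from NIfTI-1
#'
#' @param path File written by [write_volume()] (any NIfTI-1 volume works;
#'   the orientation tag defaults to transaxial if absent).
#' @return A [recon_volume()].
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  h <- RNifti::niftiHeader(img)
  orient <- sub("^orientation=", "", h$descrip)
  if (!orient %in% c("transaxial", "SA", "VLA", "HLA")) orient <- "transaxial"
  vals <- as.array(img)
  attributes(vals) <- list(dim = dim(vals)) # drop NIfTI image attributes
  vals[vals < 0] <- 0
  recon_volume(vals, voxel_mm = round(h$pixdim[2], 6), orientation = orient)
}
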