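# Shared small fixtures: a 16^3 phantom with an 8-view arc keeps the
# projector and OSEM tests fast while exercising the same code paths as the
# clinical-size 64^3 / 32-view geometry.

small_geometry <- function(n_views = 8L) {
  acquisition_geometry(n_views = n_views, detector_rows = 16L,
                       detector_cols = 16L)
}

small_phantom <- function(defects = list(), seed = 1L) {
  make_phantom(lv = lv_parameters(semi_axes_mm = c(24, 24, 30), wall_mm = 10),
               defects = defects, grid_size = 16L, seed = seed)
}

small_counts <- function(total = 2e4, seed = 1L, n_views = 8L) {
  ph <- small_phantom(seed = seed)
  sample_counts(project(ph, small_geometry(n_views)), total, seed = seed)
}

# Clinical-size standard-dose acquisition from a risk-stratified phantom.
full_counts <- function(risk = "healthy", seed = 1L, total = 2e5) {
  ph <- random_phantom(risk, seed = seed)
  sample_counts(project(ph), total,
                seed = substream_seed(seed, "poisson_fixture"))
}

# Tiny two-block architecture: same layer types as the clinical model but
# 8 x 8 inputs, for fast structural and determinism checks.
tiny_spec <- function(dropout_rate = 0) {
  gan_spec(encoder_filters = c(4L, 8L), decoder_filters = c(8L, 1L),
           encoder_bn_blocks = 2L, dropout_rate = dropout_rate,
           disc_filters = c(4L, 8L), disc_strides = c(2L, 1L))
}
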