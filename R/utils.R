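# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_param <- function(msg) stop(msg, call. = FALSE)

assert_scalar_prob <- function(p, name = "p") {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    abort_param(sprintf("`%s` must be a single probability in [0, 1]", name))
  }
}

#' Derive a reproducible seed for a named random substream
#'
#' Every stochastic stage of the pipeline (phantom generation, Poisson
#' sampling, thinning, gating, network training) draws its seed from a single
#' master seed through this function, so stages can be re-run in isolation
#' while the full pipeline stays deterministic.
#'
#' @param master Integer master seed.
#' @param stream Character name of the substream (e.g. `"poisson"`).
#' @param index Optional nonnegative integer distinguishing repeated draws
#'   within a stream (e.g. the phantom number).
#' @return A single integer in `[1, 2^31 - 2]`, deterministic in its inputs.
#' @examples
#' substream_seed(42, "thinning", 3)
#' @export
substream_seed <- function(master, stream, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  m <- 2147483647 # 2^31 - 1, Mersenne prime modulus
  h <- as.numeric(master) %% m
  for (code in utf8ToInt(stream)) {
    h <- (h * 131 + code) %% m
  }
  h <- (h * 131 + as.numeric(index)) %% m
  # avoid the degenerate 0 seed
  as.integer(h %% (m - 1)) + 1L
}

# Run an expression with a local RNG state (restores the caller's state).
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
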