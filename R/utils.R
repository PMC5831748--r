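# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Rounding used for all reported percentages: ties go away from zero
#' (so 56.5 -> 57, -56.5 -> -57), unlike base R's round-half-even.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places.
#' @return numeric vector of the same length.
#' @keywords internal
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Derive a per-stage child seed from a master seed
#'
#' A single master seed fans out to one child seed per stochastic stage via a
#' fixed affine map modulo a Mersenne prime, so that stages are individually
#' reproducible and adding a stage never perturbs another stage's stream.
#'
#' @param seed master seed (integer).
#' @param stage stage name, one of the documented stage labels.
#' @return an integer in `[1, 2^31 - 2]` suitable for [set.seed()].
#' @export
stage_seed <- function(seed, stage) {
  offsets <- c(
    genome = 101L, operons = 211L, attribute = 307L, de = 401L,
    counts = 503L, overlap = 601L, cluster_null = 701L, pipeline = 809L
  )
  if (!stage %in% names(offsets)) {
    stop("unknown stage '", stage, "'", call. = FALSE)
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  # 2^31 - 1 is prime; multiplier is the classic MINSTD constant.
  as.integer((abs(seed) * 48271 + offsets[[stage]]) %% 2147483647)
}

# stop() with a consistent package-style message, no call
abort <- function(...) stop(..., call. = FALSE)

# sample() treats a length-1 numeric x as 1:x; this always samples from
# the elements of x.
sample_one <- function(x, prob = NULL) {
  if (length(x) == 1L) x else sample(x, 1L, prob = prob)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

check_probability <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0 | x > 1)) {
    abort("'", name, "' must lie in [0, 1]")
  }
  invisible(x)
}
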