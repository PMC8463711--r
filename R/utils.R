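# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Deterministic sub-stream seeds: one master seed, one derived seed per
# table/stage, kept inside 32-bit integer range.
substream_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 7919 + offset * 104729) %% 2147483647L)
}

# Min-max scale to [0, 1]; errors if the vector is constant because the
# scaling (and hence the composite index) would be undefined.
minmax_scale <- function(x, what = "component") {
  rng <- range(x, na.rm = TRUE)
  if (!all(is.finite(rng))) {
    stop("cannot scale '", what, "': no finite values", call. = FALSE)
  }
  if (rng[1] == rng[2]) {
    stop(
      "'", what, "' is constant across species; min-max scaling is ",
      "undefined. Exclude the constant trait or add species that vary.",
      call. = FALSE
    )
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

assert_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lower || x > upper) {
    stop(
      "'", name, "' must be a single number in [", lower, ", ", upper, "]",
      call. = FALSE
    )
  }
  invisible(x)
}
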