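# Internal helpers shared across modules.

#' Derive a stage seed from the master seed
#'
#' All randomness in the package flows from one master seed. Stages and
#' repeated sub-draws receive seeds derived deterministically by this rule:
#' `(seed * 1009 + 97 * stream) mod (2^31 - 1)`, which keeps derived seeds
#' inside the 32-bit integer range while separating streams.
#'
#' @param seed Master integer seed.
#' @param stream Small non-negative integer identifying the consumer.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stream = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(as.numeric(seed)) * 1009 + 97 * as.numeric(stream)) %% 2147483647)
}

# 2D rotation matrix, counter-clockwise positive.
rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L, 2L)
}

# Wrap an angle into (-pi, pi].
wrap_angle <- function(theta) {
  out <- (theta + pi) %% (2 * pi) - pi
  ifelse(out <= -pi, out + 2 * pi, out)
}

# Row-wise Euclidean norms of a matrix.
row_norms <- function(m) sqrt(rowSums(m^2))

# Unit vector (errors on zero input).
unitize_vec <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) abort("cannot normalize a zero vector")
  v / n
}

# Standard error of the mean; NA for n < 2.
sem <- function(x) {
  n <- sum(!is.na(x))
  if (n < 2L) return(NA_real_)
  stats::sd(x, na.rm = TRUE) / sqrt(n)
}

# Closed group and tracer vocabularies for labelled-cell tables.
group_levels <- function() c("WT", "P6", "P12", "B2KO")
tracer_levels <- function() c("red", "green")
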