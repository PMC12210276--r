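# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

check_fraction <- function(x, field, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop_field(field, sprintf("must be a single number in [%g, %g]", lo, hi))
  x
}

check_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x))
    stop_field(field, sprintf("must be a single integer >= %d", min))
  as.integer(x)
}

check_positive <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop_field(field, "must be a single positive number")
  x
}

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; time-to-sample index conversion in
#' this package uses round-half-up (away from zero) so that window boundaries
#' are deterministic and independent of the parity of the sample index.
#'
#' @param x numeric vector.
#' @return integer vector.
#' @keywords internal
round_half_up <- function(x) {
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

geo_mean <- function(x) exp(mean(log(x)))

# Deterministic, exact 1-D 2-means split: returns the threshold (midpoint
# between the two cluster means) minimizing within-cluster sum of squares.
split_two_means <- function(x) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n < 2L || x[1] == x[n]) return(NA_real_)
  best <- Inf; best_k <- 1L
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  for (k in 1L:(n - 1L)) {
    ss1 <- cs2[k] - cs[k]^2 / k
    ss2 <- (cs2[n] - cs2[k]) - (cs[n] - cs[k])^2 / (n - k)
    if (ss1 + ss2 < best) { best <- ss1 + ss2; best_k <- k }
  }
  (mean(x[1:best_k]) + mean(x[(best_k + 1L):n])) / 2
}
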