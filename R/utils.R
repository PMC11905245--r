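# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if <- function(cond, ..., call. = FALSE) {
  if (cond) stop(..., call. = call.)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Derive a child RNG seed from a parent seed
#'
#' All randomness in the cohort generator flows from one integer seed; child
#' seeds for patients, groups and plans are derived with a fixed integer
#' hash so that any sub-object can be regenerated in isolation.
#'
#' @param seed parent integer seed.
#' @param ... integer indices identifying the child stream (e.g. patient
#'   number, group number).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
split_seed <- function(seed, ...) {
  idx <- c(...)
  m <- 2147483629  # largest prime < 2^31
  h <- as.numeric(seed) %% m
  mult <- c(1000003, 10007, 101, 7919, 104729)
  for (i in seq_along(idx)) {
    h <- (h * mult[((i - 1L) %% length(mult)) + 1L] + as.numeric(idx[i]) + 1) %% m
  }
  as.integer(h)
}

# round half away from zero, matching how clinical tables are printed
# (base round() uses banker's rounding, which 26.05 -> 26.0 would spoil)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
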