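`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child seed from a master seed
#'
#' Deterministic stream splitting for nested simulations: every field of a
#' simulated experiment gets its own seed derived from the design seed, so a
#' run can be reproduced bit-for-bit from its manifest. Uses a Lehmer-style
#' mix kept strictly below 2^31.
#'
#' @param seed master seed (integer).
#' @param index non-negative integer stream index.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            is.numeric(index), all(index >= 0))
  m <- 2147483647
  s <- ((abs(seed) %% m) * 48271 + (index %% m) * 16807 + 12345) %% m
  s <- (s * 69621) %% m
  as.integer(s %% (m - 1) + 1)
}

assert_pair <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 2L || anyNA(x))
    stop(sprintf("'%s' must be a numeric (min, max) pair", name), call. = FALSE)
  if (x[1] > x[2])
    stop(sprintf("'%s' must satisfy min <= max", name), call. = FALSE)
  if (positive && x[1] <= 0)
    stop(sprintf("'%s' must be strictly positive", name), call. = FALSE)
  invisible(x)
}

assert_scalar <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (strict && x <= min)
    stop(sprintf("'%s' must be > %s", name, min), call. = FALSE)
  if (!strict && x < min)
    stop(sprintf("'%s' must be >= %s", name, min), call. = FALSE)
  invisible(x)
}

assert_count <- function(x, name, min = 0L) {
  assert_scalar(x, name, min = min)
  if (x != round(x))
    stop(sprintf("'%s' must be an integer", name), call. = FALSE)
  invisible(as.integer(x))
}
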