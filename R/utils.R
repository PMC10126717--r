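#' @keywords internal
"_PACKAGE"

#' Derive a child seed from a root seed
#'
#' Deterministic seed splitting so that every trial and session of a
#' simulation is independently reproducible from one root seed. Uses a
#' Lehmer-style multiplicative step over the Mersenne prime 2^31 - 1, so
#' derived seeds always fit a 32-bit integer.
#'
#' @param seed integer root seed.
#' @param index non-negative integer stream index.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(index))
  m <- 2147483647 # 2^31 - 1
  x <- (as.double(seed) %% m + 1)
  for (i in seq_len(2)) {
    x <- (x * 48271 + as.double(index) * 16807 + 12345) %% m
  }
  as.integer(x %% (m - 2) + 1)
}

# internal: stop with a message unless condition holds
check_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
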