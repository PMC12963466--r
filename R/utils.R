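#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic 32-bit seed mixing for named substreams. Every random
# procedure in the package draws from a seed derived this way, so a study
# manifest (master seed + labels) regenerates results bit-exactly.
#' @noRd
mix_seed <- function(master, ...) {
  parts <- c(...)
  h <- as.double(master %% 2147483647L)
  for (p in parts) {
    codes <- if (is.character(p)) utf8ToInt(p) else as.integer(round(as.numeric(p) * 1000))
    for (k in codes) {
      h <- (h * 31 + (as.double(k) %% 65536)) %% 2147483647
    }
  }
  as.integer(h %% 2147483646) + 1L
}

#' @noRd
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

#' @noRd
is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
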