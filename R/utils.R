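# Internal helpers shared across modules.

# Derive a deterministic 32-bit substream seed from a master seed and a
# string label, so each generator has its own stream and adding a call to
# one generator never perturbs another.
stream_seed <- function(seed, ...) {
  label <- paste(c(...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 1013904223
  as.integer((as.numeric(seed) * 2654435 + h) %% 2147483647L)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}

# Floor a positive number to `digits` significant figures (truncation, not
# rounding): 4.2553 -> 4.2, 0.186 -> 0.18, 1.0 -> 1. Vectorised; NA passes
# through; exact zero stays zero.
signif_floor <- function(x, digits = 2) {
  vapply(x, function(xi) {
    if (is.na(xi) || xi == 0) return(xi)
    stopifnot(xi > 0)
    k <- digits - 1 - floor(log10(xi))
    # tiny guard so values that are exactly representable (e.g. 1.0) do not
    # get floored down by floating-point fuzz
    floor(xi * 10^k + 1e-9) / 10^k
  }, numeric(1))
}

# Display string for a truncated percentage: always `digits` significant
# figures, so 1 -> "1.0", 4.5 -> "4.5", 0.18 -> "0.18".
format_sigfig <- function(x, digits = 2) {
  vapply(x, function(xi) {
    if (is.na(xi)) return(NA_character_)
    if (xi == 0) return("0.0")
    dec <- max(0, digits - 1 - floor(log10(xi)))
    sprintf(paste0("%.", dec, "f"), xi)
  }, character(1))
}
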