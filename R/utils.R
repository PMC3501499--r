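#' Round half away from zero
#'
#' Reporting-layer rounding used for all per-mil values in rendered tables:
#' ties round away from zero (26.45 -> 26.5, -26.45 -> -26.5), unlike base
#' [round()]'s round-half-even. Internal arithmetic is never rounded.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places (default 1, i.e. 0.1 per mil).
#' @return numeric vector rounded to `digits` places.
#' @export
#' @examples
#' round_report(c(10.85, -10.85, 11.14))
round_report <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# sample SD (n-1); NA (not 0) for n == 1, as in +/-1 sigma table reporting
sample_sd <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x)
}

# stop() with a condition class so callers can test error families
rodiso_stop <- function(class, msg, call. = FALSE) {
  cond <- structure(
    class = c(class, "rodiso_error", "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  )
  stop(cond)
}

rodiso_warn <- function(class, msg) {
  cond <- structure(
    class = c(class, "rodiso_warning", "warning", "condition"),
    list(message = msg, call = NULL)
  )
  warning(cond)
}

# deterministic 32-bit substream seed from a master seed and stream labels
substream_seed <- function(master, ...) {
  labs <- c(...)
  s <- as.double(master) %% 2147483647
  for (k in labs) {
    s <- (s * 48271 + as.double(k) * 16807 + 11) %% 2147483647
  }
  as.integer(s)
}
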