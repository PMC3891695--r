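#' Round half away from zero
#'
#' Rounding used for all reported percentages. Base `round()` rounds half to
#' even; survey tables conventionally round half away from zero (92.5 -> 93).
#'
#' @param x numeric vector.
#' @param digits integer, decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# order-statistic quantile (type 1): smallest x with empirical CDF >= p
quantile_type1 <- function(x, p) {
  stopifnot(length(x) >= 1, p >= 0, p <= 1)
  s <- sort(x)
  s[max(1L, ceiling(p * length(s)))]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_id <- function(id, fmt, ...) {
  stop(structure(
    class = c(paste0("pasturediff_", id), "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}
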