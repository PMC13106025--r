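#' Convert a pacing rate to its cycle interval
#'
#' Programmed rates (lower rate limit, maximum tracking rate, PMT detection
#' rate, atrial flutter response rate) are expressed in pulses per minute;
#' all internal timing runs in integer milliseconds. The conversion is
#' `round(60000 / ppm)`, so e.g. 70 ppm -> 857 ms, 130 ppm -> 462 ms,
#' 95 ppm -> 632 ms.
#'
#' @param ppm pacing rate in pulses (or beats) per minute; must be > 0.
#' @return integer interval in milliseconds.
#' @export
#' @examples
#' ppm_to_interval_ms(70)   # 857
#' ppm_to_interval_ms(130)  # 462
ppm_to_interval_ms <- function(ppm) {
  stopifnot(is.numeric(ppm), all(ppm > 0))
  as.integer(round(60000 / ppm))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

as_int1 <- function(x, what) {
  if (length(x) != 1L || is.na(x) || !is.numeric(x) || x != round(x)) {
    stop(sprintf("'%s' must be a single non-missing integer value", what),
         call. = FALSE)
  }
  as.integer(x)
}
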