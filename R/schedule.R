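#' Default multi-echo sampling schedule
#'
#' The study design acquires the sodium decay curve three times with staggered
#' echo offsets, eight echoes per acquisition, giving 24 echo times between
#' 0.20 and 70.78 ms. `default_echo_schedule()` returns the sorted merge of
#' the three acquisition lists.
#'
#' @return Numeric vector of 24 strictly increasing echo times in milliseconds.
#' @examples
#' te <- default_echo_schedule()
#' length(te) # 24
#' range(te)  # 0.20 70.78
#' @export
default_echo_schedule <- function() {
  acq1 <- c(0.20, 9.70, 19.20, 28.70, 38.20, 47.70, 57.20, 66.70)
  acq2 <- c(1.56, 11.06, 20.56, 30.06, 39.56, 49.06, 58.56, 68.06)
  acq3 <- c(4.28, 13.78, 23.28, 32.78, 42.28, 51.78, 61.28, 70.78)
  sort(c(acq1, acq2, acq3))
}

# Validate an echo schedule: strictly increasing positive TEs in ms.
validate_echo_schedule <- function(te) {
  if (!is.numeric(te) || length(te) < 1 || anyNA(te)) {
    abort("echo schedule must be a numeric vector without missing values")
  }
  if (any(te <= 0)) abort("all echo times must be > 0 ms")
  if (is.unsorted(te, strictly = TRUE)) {
    abort("echo times must be strictly increasing")
  }
  invisible(te)
}
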