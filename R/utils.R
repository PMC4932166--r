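# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Decimal rounding with the half-up convention used when comparing against
#' values printed at fixed precision (base `round()` rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits.
#' @return Numeric vector rounded half-up at `digits` decimals.
#' @examples
#' round_half_up(2.5, 0)   # 3
#' round_half_up(95.14, 1) # 95.1
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

abort_oculoemg <- function(message, class) {
  abort(message, class = c(paste0("oculoemg_", class), "oculoemg_error"))
}

stop_invalid_argument <- function(message) abort_oculoemg(message, "invalid_argument")

assert_scalar_number <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid_argument(sprintf("`%s` must be a single finite number.", name))
  }
  if ((strict && x <= lower) || (!strict && x < lower)) {
    stop_invalid_argument(sprintf(
      "`%s` must be %s %s.", name, if (strict) "greater than" else "at least", lower
    ))
  }
  invisible(x)
}

# Deterministic small-integer seed mixing, kept below 2^31.
derive_seed <- function(base_seed, ...) {
  idx <- c(...)
  s <- as.double(base_seed) %% 2147483647
  for (k in seq_along(idx)) {
    s <- (s * 1103 + as.double(idx[k]) * 12289 + 7919 * k) %% 2147483647
  }
  as.integer(s)
}

recording_channels <- c("ch1_dc", "ch2_dc", "ch3_ac", "ch4_ac", "ch5_emg", "ch6_emg")

assert_recording <- function(recording) {
  missing_cols <- setdiff(c("t", recording_channels), names(recording))
  if (length(missing_cols) > 0) {
    stop_invalid_argument(paste0(
      "`recording` is missing required column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (anyNA(recording[c("t", recording_channels)])) {
    stop_invalid_argument("`recording` contains missing values.")
  }
  invisible(recording)
}

#' Sampling rate of a recording
#'
#' Returns the `sampling_rate` attribute if present, otherwise infers it from
#' the median spacing of the time column.
#'
#' @param recording A recording tibble with a `t` column (seconds).
#' @return Sampling rate in Hz.
#' @export
recording_fs <- function(recording) {
  fs <- attr(recording, "sampling_rate")
  if (!is.null(fs)) return(fs)
  if (nrow(recording) < 2) {
    stop_invalid_argument("Cannot infer sampling rate from fewer than 2 samples.")
  }
  1 / median(diff(recording$t))
}
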