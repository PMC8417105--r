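# Master timebase: every timestamp in the emulator is an integer count of
# master ticks from session start. The default 10 us tick divides all module
# clocks: ADC sample periods (50/100/200 us for 20/10/5 kSps), the 100 us
# network update step, and the 10 us minimum stimulus phase width.

ADC_RATES <- c(5000L, 10000L, 20000L)
SNN_STEP_US <- 100L
MIN_PULSE_WIDTH_US <- 10L

#' Master timebase
#'
#' Defines the tick that all timestamps in a session are counted in, and the
#' derived periods of the module clocks (ADC sample periods, network update
#' step, minimum stimulus phase width) expressed in ticks.
#'
#' @param tick_us Microseconds per master tick. Must divide every supported
#'   ADC sample period (50, 100, 200 us), the 100 us network update step and
#'   the 10 us minimum stimulus phase width. Default 10.
#' @return An object of class `"timebase"`: a list with `tick_us`,
#'   `snn_step_ticks`, `min_pulse_width_ticks` and `adc_period_ticks` (named
#'   by sample rate).
#' @examples
#' tb <- timebase()
#' tb$adc_period_ticks[["20000"]]  # 5 ticks of 10 us = 50 us
#' @export
timebase <- function(tick_us = 10L) {
  tick_us <- as.integer(tick_us)
  if (length(tick_us) != 1L || is.na(tick_us) || tick_us <= 0L)
    stop("tick_us must be a single positive integer", call. = FALSE)
  adc_period_us <- 1e6 / ADC_RATES
  clocks <- c(adc_period_us, SNN_STEP_US, MIN_PULSE_WIDTH_US)
  if (any(clocks %% tick_us != 0))
    stop("tick_us = ", tick_us, " does not divide all module clock periods ",
         "(ADC 50/100/200 us, network step 100 us, minimum pulse width 10 us)",
         call. = FALSE)
  structure(list(
    tick_us = tick_us,
    snn_step_ticks = SNN_STEP_US %/% tick_us,
    min_pulse_width_ticks = MIN_PULSE_WIDTH_US %/% tick_us,
    adc_period_ticks = stats::setNames(as.integer(adc_period_us %/% tick_us),
                                       as.character(ADC_RATES))
  ), class = "timebase")
}

#' @export
print.timebase <- function(x, ...) {
  cat("<timebase> ", x$tick_us, " us/tick; network step ", x$snn_step_ticks,
      " ticks; ADC periods ", paste(x$adc_period_ticks, collapse = "/"),
      " ticks\n", sep = "")
  invisible(x)
}

#' Convert between physical time and ticks
#'
#' Millisecond, microsecond and second quantities are rounded to the nearest
#' whole tick. Timestamps are plain doubles holding exact integers (a 24 h
#' session at 10 us/tick exceeds the 32-bit integer range).
#'
#' @param x Time value(s).
#' @param tb A [timebase()].
#' @return Tick count(s), as doubles holding whole numbers.
#' @export
ms_to_ticks <- function(x, tb = timebase()) round(x * 1000 / tb$tick_us)

#' @rdname ms_to_ticks
#' @export
us_to_ticks <- function(x, tb = timebase()) round(x / tb$tick_us)

#' @rdname ms_to_ticks
#' @export
s_to_ticks <- function(x, tb = timebase()) round(x * 1e6 / tb$tick_us)

#' @rdname ms_to_ticks
#' @export
ticks_to_ms <- function(x, tb = timebase()) x * tb$tick_us / 1000

#' Sample period of an ADC rate in master ticks
#' @param sample_rate Samples per second; one of 5000, 10000, 20000.
#' @param tb A [timebase()].
#' @return Integer number of ticks between successive samples.
#' @export
sample_period_ticks <- function(sample_rate, tb = timebase()) {
  key <- as.character(sample_rate)
  if (!key %in% names(tb$adc_period_ticks))
    stop("unsupported sample_rate ", sample_rate,
         "; must be one of ", paste(ADC_RATES, collapse = ", "), call. = FALSE)
  tb$adc_period_ticks[[key]]
}
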