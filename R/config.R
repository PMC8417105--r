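# Experiment configuration: channels, bandpass, event generators, stimulation
# conditions and the optional on-board network, validated as a whole before a
# session is simulated.

#' Recording channel configuration
#'
#' @param channel_id 0-based channel index.
#' @param mode `"differential"` (up to 16 channels) or `"single_ended"`
#'   (up to 32).
#' @param sample_rate Samples per second; one of 5000, 10000 or 20000,
#'   individually settable per channel.
#' @param enabled Whether the channel is recorded.
#' @return An object of class `"channel_config"`.
#' @export
channel_config <- function(channel_id, mode = c("differential", "single_ended"),
                           sample_rate = 20000, enabled = TRUE) {
  mode <- match.arg(mode)
  sample_rate <- as.integer(sample_rate)
  if (!sample_rate %in% ADC_RATES)
    stop("invalid sample_rate: ", sample_rate, " (field sample_rate); ",
         "must be one of ", paste(ADC_RATES, collapse = ", "), call. = FALSE)
  if (channel_id < 0) stop("channel_id must be >= 0", call. = FALSE)
  structure(list(channel_id = as.integer(channel_id), mode = mode,
                 sample_rate = sample_rate, enabled = isTRUE(enabled)),
            class = "channel_config")
}

#' Full device / experiment configuration
#'
#' Collects everything needed to run a session: the master timebase, the
#' recording channels, the global bandpass applied to all physiological
#' channels, up to eight event generators, up to eight stimulation conditions
#' (each with up to six waveforms), an optional spiking network, the global
#' stimulus refractory period and the stimulator compliance voltage.
#'
#' @param channels List of [channel_config()] objects.
#' @param bandpass Length-2 numeric: low cut (0.1--2000 Hz) and high cut
#'   (100--20000 Hz) of the amplifier bandpass. The high cut must lie below
#'   half the lowest enabled sample rate.
#' @param event_generators List of up to 8 [event_generator()] specs.
#' @param conditions List of up to 8 [stim_condition()] objects.
#' @param snn Optional [snn_network()].
#' @param seed Integer seed; every stochastic component derives its own
#'   stream from `(seed, component id)` so modules reproduce in isolation.
#' @param refractory_ms Global stimulus refractory period in ms (default 10):
#'   after a pulse-train onset no train may start on any channel for this
#'   long. Set 0 to disable.
#' @param compliance_v Stimulator compliance voltage, 50 or 60 V.
#' @param tb A [timebase()].
#' @return An object of class `"device_config"` (unvalidated; see
#'   [validate_config()]).
#' @export
device_config <- function(channels, bandpass = c(0.1, 5000),
                          event_generators = list(), conditions = list(),
                          snn = NULL, seed = 1L, refractory_ms = 10,
                          compliance_v = 60, tb = timebase()) {
  structure(list(
    timebase = tb,
    channels = channels,
    bandpass = as.numeric(bandpass),
    event_generators = event_generators,
    conditions = conditions,
    snn = snn,
    seed = as.integer(seed),
    refractory_ms = refractory_ms,
    compliance_v = compliance_v,
    validated = FALSE
  ), class = "device_config")
}

#' Validate a device configuration
#'
#' Checks every structural invariant of the configuration -- channel counts
#' (at most 16 differential or 32 single-ended), sample rates, the Nyquist
#' rule (bandpass high cut below half the lowest enabled sample rate), at
#' most 8 event generators and 8 conditions with at most 6 waveforms each --
#' and fills in the derived tick quantities. Validation is idempotent:
#' validating an already-validated configuration returns an identical object.
#'
#' @param config A [device_config()].
#' @return The normalized configuration with `validated = TRUE` and a
#'   `derived` element (per-channel sample period in ticks, refractory in
#'   ticks).
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "device_config"))
  tb <- config$timebase
  chans <- config$channels
  if (length(chans) == 0L) stop("no channels configured (field channels)", call. = FALSE)
  modes <- vapply(chans, `[[`, "", "mode")
  n_diff <- sum(modes == "differential")
  n_se <- sum(modes == "single_ended")
  if (n_diff > 16L)
    stop("channel-count violation: ", n_diff,
         " differential channels configured, at most 16 allowed (field channels)",
         call. = FALSE)
  if (n_se > 32L)
    stop("channel-count violation: ", n_se,
         " single-ended channels configured, at most 32 allowed (field channels)",
         call. = FALSE)
  rates <- vapply(chans, `[[`, 0L, "sample_rate")
  if (!all(rates %in% ADC_RATES))
    stop("invalid sample rate (field channels$sample_rate)", call. = FALSE)
  ids <- vapply(chans, `[[`, 0L, "channel_id")
  if (anyDuplicated(ids)) stop("duplicate channel_id (field channels)", call. = FALSE)

  bp <- config$bandpass
  if (length(bp) != 2L || bp[1] < 0.1 || bp[1] > 2000)
    stop("bandpass low cut must be in [0.1, 2000] Hz (field bandpass)", call. = FALSE)
  if (bp[2] < 100 || bp[2] > 20000)
    stop("bandpass high cut must be in [100, 20000] Hz (field bandpass)", call. = FALSE)
  if (bp[1] >= bp[2])
    stop("bandpass low cut must be below high cut (field bandpass)", call. = FALSE)
  enabled <- vapply(chans, `[[`, TRUE, "enabled")
  if (any(enabled)) {
    min_rate <- min(rates[enabled])
    if (bp[2] >= min_rate / 2)
      stop("Nyquist violation: bandpass high cut ", bp[2],
           " Hz is not below half the lowest enabled sample rate (",
           min_rate, " Sps) (field bandpass)", call. = FALSE)
  }

  if (length(config$event_generators) > 8L)
    stop("at most 8 event generators allowed (field event_generators)", call. = FALSE)
  if (length(config$conditions) > 8L)
    stop("at most 8 stimulation conditions allowed (field conditions)", call. = FALSE)
  for (cond in config$conditions) {
    if (length(cond$waveforms) > 6L)
      stop("at most 6 waveforms per condition (field conditions$waveforms, condition ",
           cond$condition_id, ")", call. = FALSE)
    for (w in cond$waveforms) validate_waveform(w)
  }
  if (!config$compliance_v %in% c(50, 60))
    stop("compliance_v must be 50 or 60 (field compliance_v)", call. = FALSE)
  if (config$refractory_ms < 0)
    stop("refractory_ms must be >= 0 (field refractory_ms)", call. = FALSE)
  if (!is.null(config$snn)) stopifnot(inherits(config$snn, "snn_network"))

  config$derived <- list(
    sample_period_ticks = stats::setNames(
      vapply(rates, sample_period_ticks, 0L, tb = tb), as.character(ids)),
    refractory_ticks = ms_to_ticks(config$refractory_ms, tb),
    snn_step_ticks = tb$snn_step_ticks
  )
  config$validated <- TRUE
  config
}

#' @export
print.device_config <- function(x, ...) {
  cat("<device_config> ", length(x$channels), " channels, bandpass ",
      x$bandpass[1], "-", x$bandpass[2], " Hz, ",
      length(x$event_generators), " event generators, ",
      length(x$conditions), " conditions",
      if (!is.null(x$snn)) ", with network" else "",
      if (isTRUE(x$validated)) " [validated]" else "", "\n", sep = "")
  invisible(x)
}

#' Analog storage budget of a recording
#'
#' Exact integer arithmetic for the analog payload of a session: the sum over
#' channels of sample rate times duration times bytes per sample. A 24 h
#' recording of 32 channels at 20 kSps and 2 bytes/sample is about 110.6 GB,
#' which fits the device's 128 GB removable card. Timestamp-record overhead
#' is reported separately as an estimate, not included in the total.
#'
#' @param n_channels Number of recorded channels.
#' @param rates Sample rate per channel (recycled to `n_channels`).
#' @param duration_s Recording duration in seconds.
#' @param bytes_per_sample Bytes per stored sample (default 2, 16-bit codes).
#' @return Total analog payload in bytes (double, exact).
#' @examples
#' storage_budget(32, 20000, 86400)  # 110,592,000,000 bytes
#' @export
storage_budget <- function(n_channels, rates, duration_s, bytes_per_sample = 2) {
  if (any(c(n_channels, rates, duration_s, bytes_per_sample) <= 0))
    stop("all storage_budget arguments must be positive", call. = FALSE)
  rates <- rep_len(rates, n_channels)
  sum(rates * duration_s * bytes_per_sample)
}
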