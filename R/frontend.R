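# Analog front-end and on-board DSP model: per-channel DC-blocking high-pass,
# the amplifier's adjustable bandpass, 16-bit ADC quantization with input
# noise and clipping, post-stimulus fast-settle blanking, accelerometer
# sampling, and the 8-slot IIR filter bank.

#' ADC model
#'
#' The amplifier digitizes a +/-5 mV input range at 16-bit resolution with
#' 2.4 uV RMS input-referred noise. The 192x hardware gain is folded into the
#' mV-to-code mapping: one code step is 10 mV / 65536 (~0.1526 uV) and code 0
#' corresponds to 0 mV.
#'
#' @param input_range_mv Half range in mV (default 5).
#' @param resolution_bits ADC resolution (default 16).
#' @param noise_uv_rms RMS of the additive Gaussian input noise in uV
#'   (default 2.4); set 0 to disable.
#' @return An object of class `"adc_model"` with the quantization step
#'   `lsb_mv` filled in.
#' @export
adc_model <- function(input_range_mv = 5, resolution_bits = 16,
                      noise_uv_rms = 2.4) {
  structure(list(
    input_range_mv = input_range_mv,
    resolution_bits = as.integer(resolution_bits),
    noise_uv_rms = noise_uv_rms,
    lsb_mv = 2 * input_range_mv / 2^resolution_bits,
    code_min = -2^(resolution_bits - 1),
    code_max = 2^(resolution_bits - 1) - 1
  ), class = "adc_model")
}

# one-pole RC high-pass as a difference equation; removes DC in steady state
one_pole_highpass_coef <- function(fc, fs) {
  rc <- 1 / (2 * pi * fc)
  dt <- 1 / fs
  a1 <- rc / (rc + dt)
  list(b = a1 * c(1, -1), a = c(1, -a1))
}

#' Front-end DC-blocking high-pass
#'
#' First-order high-pass applied to each physiological channel before the
#' amplifier (0.07 Hz corner by default). Removes DC in steady state while
#' attenuating a 1 kHz component by less than 0.1%.
#'
#' @param x Numeric trace in mV, uniformly sampled.
#' @param fs Sample rate in Hz.
#' @param fc Corner frequency in Hz (default 0.07).
#' @return Filtered trace, same length as `x`.
#' @export
apply_frontend_highpass <- function(x, fs, fc = 0.07) {
  if (fs <= 0 || fc <= 0) stop("fs and fc must be positive", call. = FALSE)
  co <- one_pole_highpass_coef(fc, fs)
  as.numeric(signal::filter(co$b, co$a, x))
}

#' Amplifier bandpass
#'
#' Adjustable bandpass applied globally to physiological channels: a
#' first-order high-pass at the low cut cascaded with a Butterworth low-pass
#' (default order 2) at the high cut. Mid-band gain is within 3 dB of unity;
#' the step response after a saturating input settles with a time constant
#' proportional to the inverse of the low cut.
#'
#' @param x Numeric trace in mV.
#' @param fs Sample rate in Hz.
#' @param low_cut,high_cut Band corners in Hz; `low_cut < high_cut < fs/2`.
#' @param order Order of the Butterworth low-pass section.
#' @return Filtered trace.
#' @export
apply_bandpass <- function(x, fs, low_cut, high_cut, order = 2) {
  if (!(low_cut < high_cut)) stop("low_cut must be below high_cut", call. = FALSE)
  if (high_cut >= fs / 2)
    stop("Nyquist violation: high_cut ", high_cut, " >= fs/2 = ", fs / 2,
         call. = FALSE)
  hp <- one_pole_highpass_coef(low_cut, fs)
  y <- as.numeric(signal::filter(hp$b, hp$a, x))
  lp <- signal::butter(order, high_cut / (fs / 2), type = "low")
  as.numeric(signal::filter(lp, y))
}

#' Quantize a mV trace to signed 16-bit ADC codes
#'
#' Adds Gaussian input noise at the configured RMS (unless disabled), clips
#' to the +/-5 mV input range, and rounds to the nearest code. The mapping is
#' monotone non-decreasing and round-trips within half a code step for
#' in-range inputs when noise is off.
#'
#' @param x Trace in mV at the channel sample rate.
#' @param adc An [adc_model()].
#' @param stream Optional [rng_stream()] for the noise draws; required when
#'   noise is enabled.
#' @return Integer-valued numeric vector of codes.
#' @export
quantize_samples <- function(x, adc = adc_model(), stream = NULL) {
  if (adc$noise_uv_rms > 0) {
    if (is.null(stream))
      stop("noise is enabled: supply an rng_stream (or set noise_uv_rms = 0)",
           call. = FALSE)
    x <- x + stream_rnorm(stream, length(x), sd = adc$noise_uv_rms / 1000)
  }
  x <- pmin(pmax(x, -adc$input_range_mv), adc$input_range_mv)
  pmin(pmax(round(x / adc$lsb_mv), adc$code_min), adc$code_max)
}

#' Map ADC codes back to mV
#' @param codes Integer codes.
#' @param adc An [adc_model()].
#' @return Trace in mV.
#' @export
dequantize_codes <- function(codes, adc = adc_model()) codes * adc$lsb_mv

#' Fast-settle blanking
#'
#' After each stimulus the amplifier can drive its outputs to baseline for a
#' brief window (200--3200 us) to curtail the artifact. Samples whose time
#' falls within `[onset, onset + settle_us)` are replaced by code 0; the
#' blanked intervals are returned so downstream detection can ignore them.
#'
#' @param codes Code vector for one channel; sample `i` is taken at tick
#'   `(i-1) * period`.
#' @param sample_rate Channel sample rate in Sps.
#' @param stim_onsets_ticks Stimulus onset times in ticks.
#' @param settle_us Blanking duration, 200--3200 us.
#' @param tb A [timebase()].
#' @return List with `codes` (blanked) and `intervals` (two-column matrix of
#'   tick intervals `[start, end)`).
#' @export
apply_fast_settle <- function(codes, sample_rate, stim_onsets_ticks,
                              settle_us = 400, tb = timebase()) {
  if (settle_us < 200 || settle_us > 3200)
    stop("settle_us must be within 200-3200 us", call. = FALSE)
  period <- sample_period_ticks(sample_rate, tb)
  settle_ticks <- us_to_ticks(settle_us, tb)
  iv <- cbind(start = stim_onsets_ticks, end = stim_onsets_ticks + settle_ticks)
  if (length(stim_onsets_ticks)) {
    t_ticks <- (seq_along(codes) - 1) * period
    blank <- rep(FALSE, length(codes))
    for (k in seq_len(nrow(iv)))
      blank <- blank | (t_ticks >= iv[k, 1] & t_ticks < iv[k, 2])
    codes[blank] <- 0
  }
  list(codes = codes, intervals = iv)
}

#' Sample the 3-axis accelerometer
#'
#' Motion is recorded at 100 samples per second with a +/-2 g range and
#' 10-bit accuracy, together with a temperature reading.
#'
#' @param motion Numeric matrix (samples x 3 axes) in g, at `fs_in` Sps.
#' @param fs_in Input trace rate in Sps (multiple of 100).
#' @param temperature_c Temperature in degrees C, stored alongside.
#' @return List with `codes` (m x 3 integer matrix at 100 Sps, codes in
#'   -512..511) and `temperature_c`.
#' @export
sample_accelerometer <- function(motion, fs_in, temperature_c = 37) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 3L) stop("motion must have 3 axis columns", call. = FALSE)
  if (fs_in %% 100 != 0) stop("fs_in must be a multiple of 100 Sps", call. = FALSE)
  dec <- fs_in / 100
  idx <- seq(1L, nrow(motion), by = dec)
  g <- pmin(pmax(motion[idx, , drop = FALSE], -2), 2)
  lsb <- 4 / 2^10
  codes <- pmin(pmax(round(g / lsb), -512), 511)
  list(codes = codes, temperature_c = temperature_c, rate = 100)
}

#' Filter-bank slot
#'
#' One of up to eight parallel IIR filters computed on-board, each fed by a
#' single ADC channel or the difference of a channel pair, with optional
#' full-wave rectification and optional artifact suppression (hold the last
#' pre-stimulus value during the post-stimulus blanking window).
#'
#' @param slot_id Slot index 0--7.
#' @param source Channel id, or a length-2 vector `(a, b)` meaning `a - b`.
#' @param band `c(low, high)` corners in Hz.
#' @param order IIR order (default 2).
#' @param rectify Full-wave rectify the output.
#' @param artifact_suppress Hold the last pre-stimulus value during the
#'   blanking window after each stimulus.
#' @return An object of class `"filter_bank_slot"`.
#' @export
filter_bank_slot <- function(slot_id, source, band, order = 2,
                             rectify = FALSE, artifact_suppress = FALSE) {
  if (slot_id < 0 || slot_id > 7) stop("slot_id must be 0-7", call. = FALSE)
  if (!length(source) %in% 1:2) stop("source must be 1 or 2 channel ids", call. = FALSE)
  structure(list(slot_id = as.integer(slot_id), source = as.integer(source),
                 band = as.numeric(band), order = order,
                 rectify = isTRUE(rectify),
                 artifact_suppress = isTRUE(artifact_suppress)),
            class = "filter_bank_slot")
}

#' Run the on-board filter bank
#'
#' @param codes Numeric matrix (samples x channels); column names are channel
#'   ids as strings.
#' @param fs Sample rate of `codes` in Sps (all bank sources share it).
#' @param slots List of up to 8 [filter_bank_slot()] objects.
#' @param stim_onsets_ticks Stimulus onsets (ticks) for artifact suppression.
#' @param settle_us Blanking window used by artifact suppression.
#' @param tb A [timebase()].
#' @return Numeric matrix (samples x slots), columns named by slot id.
#' @export
run_filter_bank <- function(codes, fs, slots, stim_onsets_ticks = numeric(),
                            settle_us = 400, tb = timebase()) {
  if (length(slots) > 8L) stop("at most 8 filter-bank slots", call. = FALSE)
  out <- matrix(0, nrow(codes), length(slots),
                dimnames = list(NULL, vapply(slots, function(s) as.character(s$slot_id), "")))
  period <- sample_period_ticks(fs, tb)
  t_ticks <- (seq_len(nrow(codes)) - 1) * period
  settle_ticks <- us_to_ticks(settle_us, tb)
  for (j in seq_along(slots)) {
    s <- slots[[j]]
    src <- as.character(s$source)
    if (!all(src %in% colnames(codes)))
      stop("invalid filter-bank source channel ", paste(src, collapse = ","),
           call. = FALSE)
    x <- if (length(src) == 2L) codes[, src[1]] - codes[, src[2]] else codes[, src]
    y <- apply_bandpass(x, fs, s$band[1], s$band[2], order = s$order)
    if (s$rectify) y <- abs(y)
    if (s$artifact_suppress && length(stim_onsets_ticks)) {
      for (on in stim_onsets_ticks) {
        in_win <- which(t_ticks >= on & t_ticks < on + settle_ticks)
        if (length(in_win)) {
          hold <- if (in_win[1] > 1L) y[in_win[1] - 1L] else 0
          y[in_win] <- hold
        }
      }
    }
    out[, j] <- y
  }
  out
}
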