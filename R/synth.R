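# Synthetic scenario generation: ground-truth spike trains rendered through
# parametric templates, EMG bursts of motor-unit potentials, Gaussian noise,
# stimulus artifacts (brief biphasic transients when the coupled amplitude
# stays within the amplifier's +/-5 mV range, long saturating decays when it
# does not), and stimulus-evoked spikes. Every deviation from noise in a
# generated trace is attributable to a listed ground-truth event, so the
# rest of the emulator can be verified end-to-end without recorded data.

#' Default extracellular spike template
#'
#' Biphasic waveform with ~0.6 ms support: a sharp negative peak followed by
#' a smaller positive overshoot. Parametric and user-overridable; real
#' spike shapes vary and are not modelled beyond this morphology.
#'
#' @param fs Sample rate in Sps.
#' @param peak_mv Magnitude of the negative peak in mV.
#' @return Numeric template (mV), peak-aligned near its start.
#' @export
spike_template <- function(fs = 20000, peak_mv = 1) {
  t <- seq(0, 0.6e-3, by = 1 / fs)
  w <- -exp(-((t - 0.15e-3) / 0.07e-3)^2) + 0.45 * exp(-((t - 0.35e-3) / 0.12e-3)^2)
  peak_mv * w / max(abs(w))
}

#' Ground-truth neuron model
#'
#' @param unit_id Identifier used in the ground truth.
#' @param template Spike waveform in mV (at the scenario rate).
#' @param rate_hz Baseline firing rate (Poisson, >= 0).
#' @param refractory_ms Absolute refractory period.
#' @param coupling Amplitude multiplier per recording channel (length =
#'   number of channels; 0 = not visible on that channel).
#' @return An object of class `"neuron_model"`.
#' @export
neuron_model <- function(unit_id, template, rate_hz, refractory_ms = 1,
                         coupling = 1) {
  if (rate_hz < 0) stop("rate_hz must be >= 0", call. = FALSE)
  structure(list(unit_id = as.integer(unit_id), template = template,
                 rate_hz = rate_hz, refractory_ms = refractory_ms,
                 coupling = coupling), class = "neuron_model")
}

#' Synthetic scenario specification
#'
#' @param duration_s Scenario length in seconds.
#' @param fs Trace sample rate (default 20000 Sps).
#' @param n_channels Number of recording channels.
#' @param neurons List of [neuron_model()]s.
#' @param noise_mv_rms Per-channel noise RMS in mV (recycled).
#' @param artifact List: `coupling_uv_per_ua` (per channel, recycled),
#'   `highpass_fl` (low cut in Hz governing saturating-artifact recovery).
#' @param evoked Data frame of evoked-response rules: `unit_id`,
#'   `probability`, `latency_ms`, `jitter_ms` (one row per responsive unit).
#' @param seed Scenario seed.
#' @return An object of class `"scenario_spec"`.
#' @export
scenario_spec <- function(duration_s, fs = 20000, n_channels = 1,
                          neurons = list(), noise_mv_rms = 0.02,
                          artifact = list(coupling_uv_per_ua = 10,
                                          highpass_fl = 500),
                          evoked = NULL, seed = 1L) {
  if (!is.null(evoked)) {
    if (any(evoked$probability < 0 | evoked$probability > 1))
      stop("evoked probabilities must be in [0,1]", call. = FALSE)
    if (any(evoked$latency_ms < 0))
      stop("evoked latencies must be >= 0", call. = FALSE)
  }
  structure(list(duration_s = duration_s, fs = fs, n_channels = n_channels,
                 neurons = neurons,
                 noise_mv_rms = rep_len(noise_mv_rms, n_channels),
                 artifact = artifact, evoked = evoked,
                 seed = as.integer(seed)), class = "scenario_spec")
}

# Poisson spike times with absolute refractory; the gap distribution is
# refractory + exponential with the rate adjusted so the mean rate stays at
# rate_hz despite the dead time.
draw_spike_times <- function(rate_hz, refractory_ms, duration_s, stream) {
  if (rate_hz <= 0) return(numeric(0))
  ref <- refractory_ms / 1000
  if (rate_hz * ref >= 1)
    stop("rate incompatible with refractory period", call. = FALSE)
  rate_adj <- rate_hz / (1 - rate_hz * ref)
  out <- numeric(0); t <- 0
  repeat {
    n_guess <- max(16L, ceiling(1.5 * (duration_s - t) * rate_hz))
    gaps <- ref + stream_rexp(stream, n_guess, rate = rate_adj)
    tt <- t + cumsum(gaps)
    out <- c(out, tt[tt < duration_s])
    t <- tt[length(tt)]
    if (t >= duration_s) break
  }
  out
}

# render spikes (seconds) into the trace matrix via template and coupling
add_spikes_to_traces <- function(traces, fs, spikes_s, template, coupling) {
  n <- nrow(traces)
  coupling <- rep_len(coupling, ncol(traces))
  for (ts in spikes_s) {
    i0 <- round(ts * fs) + 1L
    idx <- i0:min(n, i0 + length(template) - 1L)
    if (idx[1] > n) next
    seg <- template[seq_along(idx)]
    for (ch in which(coupling != 0))
      traces[idx, ch] <- traces[idx, ch] + coupling[ch] * seg
  }
  traces
}

#' Synthesize a multichannel extracellular recording with ground truth
#'
#' Draws Poisson spike trains (with absolute refractory) for every neuron,
#' renders their templates onto the channels according to the coupling
#' vectors, and adds i.i.d. Gaussian noise. The ground truth is returned
#' separately and is exhaustive: with noise RMS 0 the trace is exactly the
#' sum of placed templates.
#'
#' @param spec A [scenario_spec()].
#' @return List with `traces` (samples x channels matrix, mV), `truth`
#'   (data frame `unit_id`, `time_s`, `sample`, `evoked`), `fs` and `spec`.
#' @export
synthesize_recording <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  n <- round(spec$duration_s * spec$fs)
  traces <- matrix(0, n, spec$n_channels)
  truth <- list()
  for (nm in spec$neurons) {
    stream <- rng_stream(spec$seed, paste0("unit", nm$unit_id))
    ts <- draw_spike_times(nm$rate_hz, nm$refractory_ms, spec$duration_s, stream)
    if (length(ts)) {
      traces <- add_spikes_to_traces(traces, spec$fs, ts, nm$template, nm$coupling)
      truth[[length(truth) + 1L]] <- data.frame(
        unit_id = nm$unit_id, time_s = ts, sample = round(ts * spec$fs) + 1L,
        evoked = FALSE)
    }
  }
  noise_stream <- rng_stream(spec$seed, "noise")
  for (ch in seq_len(spec$n_channels))
    if (spec$noise_mv_rms[ch] > 0)
      traces[, ch] <- traces[, ch] +
        stream_rnorm(noise_stream, n, sd = spec$noise_mv_rms[ch])
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(unit_id = integer(), time_s = numeric(), sample = integer(),
               evoked = logical())
  truth <- truth[order(truth$time_s), , drop = FALSE]
  list(traces = traces, truth = truth, fs = spec$fs, spec = spec)
}

#' Inject stimulus artifacts into traces
#'
#' For each stimulus pulse the coupled amplitude on a channel is
#' `amplitude_uA * coupling_uV_per_uA`. When that stays within the
#' amplifier's +/-5 mV input range, the artifact is a brief biphasic
#' transient confined to less than 2 ms. When it exceeds the range, the
#' amplifier saturates and the recording shows a step at the saturation
#' level decaying exponentially with time constant `1/(2*pi*fl)`, so
#' recovery time scales with the inverse of the high-pass (low cut) setting
#' -- about 0.1 s at 10 Hz.
#'
#' @param traces Samples x channels matrix (mV).
#' @param fs Trace sample rate.
#' @param pulses Pulse data frame from [schedule_pulses()] (uses `onset` and
#'   phase amplitudes), or a data frame with `onset` (ticks) and `amp1_ua`.
#' @param artifact Artifact model list (see [scenario_spec()]).
#' @param input_range_mv Amplifier input range (default 5 mV).
#' @param tb A [timebase()].
#' @return List with `traces` (modified) and `artifact_traces` (the added
#'   component alone; subtracting it restores the input exactly).
#' @export
inject_stimulus_artifact <- function(traces, fs, pulses, artifact,
                                     input_range_mv = 5, tb = timebase()) {
  n <- nrow(traces)
  art <- matrix(0, n, ncol(traces))
  coup <- rep_len(artifact$coupling_uv_per_ua, ncol(traces))
  fl <- artifact$highpass_fl
  brief_n <- round(0.0015 * fs)                    # transient support, < 2 ms
  brief_t <- seq_len(brief_n) / fs
  brief_shape <- exp(-brief_t / 3e-4) * cos(2 * pi * brief_t / 1e-3)
  tau <- 1 / (2 * pi * fl)
  for (k in seq_len(nrow(pulses))) {
    i0 <- round(pulses$onset[k] * tb$tick_us * 1e-6 * fs) + 1L
    if (i0 > n) next
    amp_ua <- pulses$amp1_ua[k]
    for (ch in seq_len(ncol(traces))) {
      a_mv <- amp_ua * coup[ch] / 1000
      if (a_mv == 0) next
      if (abs(a_mv) <= input_range_mv) {
        idx <- i0:min(n, i0 + brief_n - 1L)
        art[idx, ch] <- art[idx, ch] + a_mv * brief_shape[seq_along(idx)]
      } else {
        sat <- sign(a_mv) * input_range_mv
        len <- min(n - i0 + 1L, ceiling(8 * tau * fs))
        idx <- i0:(i0 + len - 1L)
        art[idx, ch] <- art[idx, ch] + sat * exp(-(seq_len(len) - 1L) / (fs * tau))
      }
    }
  }
  list(traces = traces + art, artifact_traces = art)
}

#' Add stimulus-evoked spikes to the ground truth
#'
#' For every stimulus and every responsive unit, with the configured
#' probability a spike is inserted at `latency + jitter` after the pulse
#' onset, unless it would violate the unit's refractory period against an
#' existing ground-truth spike. Evoked spikes are flagged.
#'
#' @param pulses Pulse data frame (uses `onset`, in ticks).
#' @param spec A [scenario_spec()] with an `evoked` table.
#' @param truth Existing ground-truth data frame (from
#'   [synthesize_recording()]).
#' @param stream An [rng_stream()] for the probability and jitter draws.
#' @param tb A [timebase()].
#' @return The updated truth data frame, sorted by time, with new rows
#'   flagged `evoked = TRUE`.
#' @export
evoke_responses <- function(pulses, spec, truth, stream, tb = timebase()) {
  ev <- spec$evoked
  if (is.null(ev) || !nrow(pulses)) return(truth)
  refr <- stats::setNames(
    vapply(spec$neurons, `[[`, 0, "refractory_ms") / 1000,
    vapply(spec$neurons, `[[`, 0L, "unit_id"))
  new <- list()
  onsets_s <- pulses$onset * tb$tick_us * 1e-6
  for (j in seq_len(nrow(ev))) {
    p <- ev$probability[j]
    hit <- stream_runif(stream, length(onsets_s)) < p
    if (!any(hit)) next
    jit <- if (ev$jitter_ms[j] > 0)
      stream_rnorm(stream, sum(hit), sd = ev$jitter_ms[j] / 1000) else 0
    t_sp <- onsets_s[hit] + ev$latency_ms[j] / 1000 + jit
    new[[length(new) + 1L]] <- data.frame(
      unit_id = ev$unit_id[j], time_s = pmax(t_sp, onsets_s[hit]),
      evoked = TRUE)
  }
  if (!length(new)) return(truth)
  new <- do.call(rbind, new)
  # drop evoked spikes violating the unit's refractory against prior spikes
  keep <- logical(nrow(new))
  for (j in seq_len(nrow(new))) {
    u <- new$unit_id[j]
    r <- refr[as.character(u)]
    if (is.na(r)) r <- 0.001
    prior <- c(truth$time_s[truth$unit_id == u], new$time_s[new$unit_id == u][seq_len(j - 1)])
    keep[j] <- !any(abs(prior - new$time_s[j]) < r)
  }
  new <- new[keep, , drop = FALSE]
  if (!nrow(new)) return(truth)
  new$sample <- round(new$time_s * spec$fs) + 1L
  out <- rbind(truth, new[, c("unit_id", "time_s", "sample", "evoked")])
  out[order(out$time_s), , drop = FALSE]
}

#' Motor-unit potential template for EMG scenarios
#' @param fs Sample rate.
#' @param peak_mv Peak magnitude in mV.
#' @return Numeric template (mV), ~4 ms support.
#' @export
mup_template <- function(fs = 5000, peak_mv = 1) {
  t <- seq(0, 4e-3, by = 1 / fs)
  w <- -exp(-((t - 1e-3) / 0.5e-3)^2) + 0.6 * exp(-((t - 2.2e-3) / 0.8e-3)^2)
  peak_mv * w / max(abs(w))
}

#' Synthesize the three-muscle EMG scenario
#'
#' Emulates the setup in which EMG from three muscles drives stimulation at
#' three spinal sites through independent discriminator loops: each channel
#' carries burst-modulated trains of motor-unit potentials over Gaussian
#' noise, with bursts staggered across channels so the loops fire
#' concurrently but not identically. Ground-truth burst windows and
#' potential times are returned per channel.
#'
#' @param duration_s Scenario length in seconds.
#' @param fs Sample rate (default 5000 Sps, an EMG-appropriate rate).
#' @param burst_rate_hz Burst onset rate per channel.
#' @param burst_dur_s Burst duration.
#' @param mup_rate_hz Motor-unit potential rate inside a burst.
#' @param peak_mv Potential peak amplitude.
#' @param noise_mv_rms Noise RMS per channel.
#' @param seed Scenario seed.
#' @return List with `traces` (samples x 3, mV), `truth` (list per channel:
#'   `bursts` data frame with start/end seconds, `potentials` times), `fs`.
#' @export
synthesize_emg_scenario <- function(duration_s = 10, fs = 5000,
                                    burst_rate_hz = 0.8, burst_dur_s = 0.35,
                                    mup_rate_hz = 60, peak_mv = 1,
                                    noise_mv_rms = peak_mv / 10, seed = 1L) {
  n <- round(duration_s * fs)
  traces <- matrix(0, n, 3)
  tmpl <- mup_template(fs, peak_mv)
  truth <- vector("list", 3)
  for (ch in 1:3) {
    stream <- rng_stream(seed, paste0("emg", ch))
    n_bursts <- max(1L, round(duration_s * burst_rate_hz))
    # staggered burst onsets: jittered grid offset per channel
    grid <- (seq_len(n_bursts) - 1) / burst_rate_hz + (ch - 1) * 0.4 / burst_rate_hz
    starts <- grid + stream_runif(stream, n_bursts, 0, 0.2 / burst_rate_hz)
    starts <- starts[starts + burst_dur_s < duration_s]
    pots <- numeric(0)
    for (b in starts) {
      k <- stream_rpois(stream, 1, lambda = mup_rate_hz * burst_dur_s)
      if (k > 0) {
        tt <- sort(b + stream_runif(stream, k, 0, burst_dur_s))
        # impose a 5 ms separation so potentials are discriminable
        keep <- c(TRUE, diff(tt) > 5e-3)
        pots <- c(pots, tt[keep])
      }
    }
    traces[, ch] <- add_spikes_to_traces(
      traces[, ch, drop = FALSE], fs, pots, tmpl, 1)[, 1]
    traces[, ch] <- traces[, ch] + stream_rnorm(stream, n, sd = noise_mv_rms)
    truth[[ch]] <- list(bursts = data.frame(start = starts,
                                            end = starts + burst_dur_s),
                        potentials = pots)
  }
  list(traces = traces, truth = truth, fs = fs)
}
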