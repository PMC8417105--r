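# Declarative experiment configuration files (YAML). Times in the file are
# given in milliseconds (the natural unit at the bench) and converted to
# master ticks on load.

#' Read a device configuration from a YAML file
#'
#' The file mirrors the experiment setup tabs: record settings (channels,
#' bandpass), event generators, stimulation conditions and the optional
#' spiking network. Intervals, delays and widths are in milliseconds.
#'
#' @param path YAML file path.
#' @return A validated [device_config()].
#' @export
read_device_config <- function(path) {
  y <- yaml::read_yaml(path)
  tb <- timebase(y$timebase$tick_us %||% 10L)
  chans <- lapply(y$channels, function(ch)
    channel_config(ch$channel_id, ch$mode %||% "single_ended",
                   ch$sample_rate %||% 20000, ch$enabled %||% TRUE))
  gens <- lapply(y$event_generators %||% list(), function(g) {
    disc <- NULL
    if (!is.null(g$discriminator)) {
      d <- g$discriminator
      wins <- lapply(d$windows, function(w)
        list(delay_ticks = ms_to_ticks(w$delay_ms, tb),
             amplitude_min = w$amplitude_min, amplitude_max = w$amplitude_max))
      disc <- window_disc_spec(d$threshold, d$polarity %||% "rising", wins,
                               ms_to_ticks(d$dead_time_ms %||% 1, tb))
    }
    event_generator(
      g$gen_id, g$mode,
      period_ticks = if (!is.null(g$period_ms)) ms_to_ticks(g$period_ms, tb),
      range_ticks = if (!is.null(g$range_ms)) ms_to_ticks(unlist(g$range_ms), tb),
      mean_ticks = if (!is.null(g$mean_ms)) ms_to_ticks(g$mean_ms, tb),
      source = g$source, discriminator = disc)
  })
  conds <- lapply(y$conditions %||% list(), function(cn) {
    wfs <- lapply(cn$waveforms %||% list(), function(w)
      stim_waveform(w$waveform_id, ms_to_ticks(w$delay_ms %||% 0, tb),
                    w$amp1_ua, ms_to_ticks(w$width1_ms, tb),
                    w$amp2_ua, ms_to_ticks(w$width2_ms, tb),
                    w$count %||% 1L, ms_to_ticks(w$ipi_ms %||% 0, tb),
                    unlist(w$pins)))
    tm <- lapply(cn$trigger_map %||% list(), function(m)
      list(gen = m$gen, waveform_ids = unlist(m$waveform_ids),
           rules = list()))
    stim_condition(cn$condition_id, wfs, tm,
                   if (!is.null(cn$duration_ms)) ms_to_ticks(cn$duration_ms, tb))
  })
  net <- NULL
  if (!is.null(y$snn)) {
    g <- y$snn$globals
    conn <- do.call(rbind, lapply(y$snn$connections, function(cc)
      data.frame(source = cc$source, target = cc$target,
                 weight_uv = cc$weight_uv)))
    net <- snn_network(y$snn$n_units,
                       snn_globals(g$conduction_delay_steps %||% 1L,
                                   g$fast_decay, g$slow_decay,
                                   g$bias_chance %||% 0L,
                                   g$bias_strength_uv %||% 0L,
                                   g$threshold_uv),
                       conn)
  }
  validate_config(device_config(
    channels = chans, bandpass = unlist(y$bandpass %||% c(0.1, 5000)),
    event_generators = gens, conditions = conds, snn = net,
    seed = y$seed %||% 1L, refractory_ms = y$refractory_ms %||% 10,
    compliance_v = y$compliance_v %||% 60, tb = tb))
}

#' Read a synthetic scenario from a YAML file
#'
#' @param path YAML file path.
#' @return A [scenario_spec()].
#' @export
read_scenario_spec <- function(path) {
  y <- yaml::read_yaml(path)
  fs <- y$fs %||% 20000
  neurons <- lapply(y$neurons %||% list(), function(nm)
    neuron_model(nm$unit_id, spike_template(fs, nm$peak_mv %||% 1),
                 nm$rate_hz, nm$refractory_ms %||% 1,
                 unlist(nm$coupling %||% 1)))
  evoked <- if (!is.null(y$evoked))
    do.call(rbind, lapply(y$evoked, function(e)
      data.frame(unit_id = e$unit_id, probability = e$probability,
                 latency_ms = e$latency_ms, jitter_ms = e$jitter_ms %||% 0)))
  scenario_spec(y$duration_s, fs, y$n_channels %||% 1, neurons,
                y$noise_mv_rms %||% 0.02,
                artifact = list(
                  coupling_uv_per_ua = unlist(y$artifact$coupling_uv_per_ua %||% 10),
                  highpass_fl = y$artifact$highpass_fl %||% 500),
                evoked = evoked, seed = y$seed %||% 1L)
}
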