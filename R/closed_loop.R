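# Closed-loop session runner: a single causal pass over the scenario at the
# ADC sample rate, wiring scenario -> front-end -> event generators (and the
# spiking network) -> stimulator, with stimulation feeding back into the
# scenario as artifacts, evoked spikes and fast-settle blanking. Everything
# is recorded to a session file.
#
# The runner assumes all enabled channels share one sample rate (that of the
# scenario); per-channel rates are supported by the offline front-end
# functions. Discriminator sources must be ADC channels here; the filter
# bank is available offline.

#' Run a closed-loop session
#'
#' Simulates a full experiment: the synthetic scenario provides ground-truth
#' traces; each sample is band-filtered and quantized; window discriminators
#' and interval generators emit events; events (optionally routed through
#' the spiking network) trigger stimulation under gating, the global
#' refractory and the rate cap; delivered pulses feed back into the traces
#' as stimulus artifacts, evoked spikes and fast-settle blanking. The
#' decision for a discriminated spike is available once its last amplitude
#' window has been tested, so the pulse onset follows the threshold crossing
#' by at most the last window delay plus one sample period plus the
#' waveform's configured delay.
#'
#' @param config A [device_config()] (validated or not).
#' @param scenario A [scenario_spec()].
#' @param path Output session file path.
#' @param settle_us Fast-settle blanking window after each pulse onset.
#' @param block_s Analog chunking granularity in the session file.
#' @return List with `path`, `pulses` (delivered pulse data frame),
#'   `rejected` (dropped triggers with reasons), `records` (all timestamp
#'   records), `truth` (ground truth incl. evoked spikes), `codes` (samples
#'   x channels matrix as recorded) and `summary` counters.
#' @export
run_closed_loop <- function(config, scenario, path = tempfile(fileext = ".nls"),
                            settle_us = 400, block_s = 1) {
  if (!isTRUE(config$validated)) config <- validate_config(config)
  stopifnot(inherits(scenario, "scenario_spec"))
  tb <- config$timebase
  fs <- scenario$fs
  period <- sample_period_ticks(fs, tb)
  settle_ticks <- us_to_ticks(settle_us, tb)

  base <- synthesize_recording(scenario)
  W <- base$traces
  truth <- base$truth
  n <- nrow(W)
  duration_ticks <- n * period

  chan_ids <- vapply(config$channels, `[[`, 0L, "channel_id")
  enabled <- vapply(config$channels, `[[`, TRUE, "enabled")
  chan_ids <- chan_ids[enabled]
  if (max(chan_ids) + 1 > ncol(W))
    stop("scenario provides fewer channels than the config enables", call. = FALSE)
  nch <- length(chan_ids)
  cols <- chan_ids + 1L

  adc <- adc_model()
  noise <- matrix(0, n, nch)
  if (adc$noise_uv_rms > 0) {
    ns <- rng_stream(config$seed, "adc_noise")
    for (j in seq_len(nch)) noise[, j] <- stream_rnorm(ns, n, sd = adc$noise_uv_rms / 1000)
  }

  # streaming filter coefficients (match the offline front-end functions)
  hp0 <- one_pole_highpass_coef(0.07, fs)$a[2] * -1
  hp1 <- one_pole_highpass_coef(config$bandpass[1], fs)$a[2] * -1
  lp <- signal::butter(2, config$bandpass[2] / (fs / 2), type = "low")
  lb <- as.numeric(lp$b); la <- as.numeric(lp$a)
  s_hp0x <- numeric(nch); s_hp0y <- numeric(nch)
  s_hp1x <- numeric(nch); s_hp1y <- numeric(nch)
  s_z1 <- numeric(nch); s_z2 <- numeric(nch)

  # interval generators: precomputed event streams
  gens <- config$event_generators
  interval_ev <- list(); interval_ptr <- list()
  disc <- list()
  snn_gen_ids <- integer(0)
  for (g in gens) {
    id <- as.character(g$gen_id)
    if (g$mode %in% c("fixed_interval", "uniform_interval", "exponential_interval")) {
      st <- rng_stream(config$seed, paste0("gen", g$gen_id))
      interval_ev[[id]] <- generate_interval_events(g, duration_ticks, st)$timestamp
      interval_ptr[[id]] <- 1L
    } else if (g$mode == "window_discriminator") {
      delays <- vapply(g$discriminator$windows, `[[`, 0, "delay_ticks")
      if (any(delays %% period != 0))
        stop("window delay not a multiple of the sample period", call. = FALSE)
      disc[[id]] <- list(gen = g, col = g$source + 1L,
                         dsamp = delays %/% period,
                         prev = NA_real_, last_accept = -Inf,
                         pending = list())
    } else if (g$mode == "snn_output") {
      snn_gen_ids <- c(snn_gen_ids, g$gen_id)
    }
  }

  # condition sequencing
  seq_out <- sequence_conditions(config$conditions, duration_ticks)
  segs <- seq_out$segments
  cond_by_id <- stats::setNames(config$conditions,
                                vapply(config$conditions, `[[`, 0L, "condition_id"))
  seg_ptr <- 1L

  # spiking network
  net <- config$snn
  snn_st <- if (!is.null(net)) snn_state(net, config$seed) else NULL
  snn_step_ticks <- tb$snn_step_ticks
  ext_flags <- logical(8)
  snn_records <- list()

  # scheduler bookkeeping (shared current source)
  sch <- scheduler_state(config$refractory_ms, config$compliance_v, tb = tb)
  busy_until <- -Inf; last_pins <- NULL
  refractory_until <- -Inf
  pulse_log <- numeric(0)
  accepted_triggers <- numeric(0)
  pulses <- list(); rejected <- list()
  dig_records <- list(); stim_records <- list()
  settle_until <- -Inf
  blank_iv <- list()
  evoked_stream <- rng_stream(config$seed, "evoked")
  neurons_by_id <- stats::setNames(
    scenario$neurons, vapply(scenario$neurons, `[[`, 0L, "unit_id"))
  codes_out <- matrix(0L, n, nch)

  active_condition <- function(t) {
    while (seg_ptr < nrow(segs) && t >= segs$end[seg_ptr]) seg_ptr <<- seg_ptr + 1L
    cond_by_id[[as.character(segs$condition_id[seg_ptr])]]
  }

  deliver_train <- function(trg_ts, decision_t, src, cond) {
    maps <- Filter(function(m) m$gen == src, cond$trigger_map)
    if (!length(maps)) return(invisible())
    wf_ids <- sort(unique(unlist(lapply(maps, `[[`, "waveform_ids"))))
    rules <- unlist(lapply(maps, `[[`, "rules"), recursive = FALSE) %||% list()
    gsrc <- Filter(function(g) g$gen_id == src, gens)
    if (length(gsrc)) rules <- c(rules, gsrc[[1]]$gate_rules)
    lv <- as.list(stats::setNames(as.double(codes_now), as.character(chan_ids)))
    gt <- gate_trigger(decision_t, rules, accepted_triggers, lv)
    if (!gt$accept) {
      rejected[[length(rejected) + 1L]] <<-
        data.frame(trigger_ts = trg_ts, source = src, reason = gt$reason)
      return(invisible())
    }
    wf_all <- stats::setNames(cond$waveforms,
                              vapply(cond$waveforms, `[[`, 0L, "waveform_id"))
    ws <- wf_all[as.character(wf_ids)]
    train_onset <- min(vapply(ws, function(w) decision_t + w$delay_ticks, 0))
    if (train_onset < refractory_until) {
      rejected[[length(rejected) + 1L]] <<-
        data.frame(trigger_ts = trg_ts, source = src, reason = "refractory")
      return(invisible())
    }
    n_train <- sum(vapply(ws, `[[`, 0L, "count"))
    cap <- min(vapply(ws, rate_cap_for, 0, compliance_v = config$compliance_v))
    in_win <- sum(pulse_log > train_onset - sch$second_ticks &
                  pulse_log <= train_onset)
    if (in_win + n_train > cap) {
      rejected[[length(rejected) + 1L]] <<-
        data.frame(trigger_ts = trg_ts, source = src, reason = "rate_cap")
      return(invisible())
    }
    req <- do.call(rbind, lapply(ws, function(w) {
      width <- w$width1_ticks + w$width2_ticks
      step <- if (w$ipi_ticks > 0) w$ipi_ticks else width
      data.frame(requested = decision_t + w$delay_ticks +
                   (seq_len(w$count) - 1L) * step,
                 waveform_id = w$waveform_id)
    }))
    req <- req[order(req$requested, req$waveform_id), , drop = FALSE]
    for (k in seq_len(nrow(req))) {
      w <- wf_all[[as.character(req$waveform_id[k])]]
      pins <- if (length(w$pins) == 2L) w$pins else c(w$pins, NA_integer_)
      earliest <- if (!is.null(last_pins) && identical(last_pins, pins))
        busy_until
      else if (is.finite(busy_until)) busy_until + sch$switch_ticks
      else -Inf
      onset <- max(req$requested[k], earliest)
      end <- onset + w$width1_ticks + w$width2_ticks
      pulses[[length(pulses) + 1L]] <<- data.frame(
        onset = onset, end = end, amp1_ua = w$amp1_ua,
        width1_ticks = w$width1_ticks, amp2_ua = w$amp2_ua,
        width2_ticks = w$width2_ticks, pin_a = pins[1], pin_c = pins[2],
        waveform_id = w$waveform_id, trigger_ts = trg_ts)
      busy_until <<- end; last_pins <<- pins
      pulse_log <<- c(pulse_log, onset)
      stim_records[[length(stim_records) + 1L]] <<- data.frame(
        timestamp = onset, source = pins[1], kind = "stimulus_event",
        p1 = w$waveform_id, p2 = 0L)
      apply_feedback(onset, w)
    }
    if (sch$refractory_ticks > 0)
      refractory_until <<- train_onset + sch$refractory_ticks
    accepted_triggers <<- c(accepted_triggers, decision_t)
    invisible()
  }

  apply_feedback <- function(onset, w) {
    i0 <- ceiling(onset / period) + 1L  # first sample at/after the onset
    # stimulus artifact on every channel
    amp_ua <- w$amp1_ua
    coup <- rep_len(scenario$artifact$coupling_uv_per_ua, ncol(W))
    fl <- scenario$artifact$highpass_fl
    if (i0 <= n) {
      for (ch in seq_len(ncol(W))) {
        a_mv <- amp_ua * coup[ch] / 1000
        if (a_mv == 0) next
        if (abs(a_mv) <= adc$input_range_mv) {
          len <- min(n - i0 + 1L, round(0.0015 * fs))
          tt <- seq_len(len) / fs
          W[i0:(i0 + len - 1L), ch] <<- W[i0:(i0 + len - 1L), ch] +
            a_mv * exp(-tt / 3e-4) * cos(2 * pi * tt / 1e-3)
        } else {
          tau <- 1 / (2 * pi * fl)
          len <- min(n - i0 + 1L, ceiling(8 * tau * fs))
          W[i0:(i0 + len - 1L), ch] <<- W[i0:(i0 + len - 1L), ch] +
            sign(a_mv) * adc$input_range_mv * exp(-(seq_len(len) - 1L) / (fs * tau))
        }
      }
    }
    # fast settle blanking
    settle_until <<- max(settle_until, onset + settle_ticks)
    blank_iv[[length(blank_iv) + 1L]] <<- c(onset, onset + settle_ticks)
    # evoked responses
    ev <- scenario$evoked
    if (!is.null(ev)) {
      onset_s <- onset * tb$tick_us * 1e-6
      for (j in seq_len(nrow(ev))) {
        if (stream_runif(evoked_stream, 1) >= ev$probability[j]) next
        jit <- if (ev$jitter_ms[j] > 0)
          stream_rnorm(evoked_stream, 1, sd = ev$jitter_ms[j] / 1000) else 0
        t_sp <- max(onset_s, onset_s + ev$latency_ms[j] / 1000 + jit)
        nm <- neurons_by_id[[as.character(ev$unit_id[j])]]
        if (is.null(nm)) next
        prior <- truth$time_s[truth$unit_id == nm$unit_id]
        if (any(abs(prior - t_sp) < nm$refractory_ms / 1000)) next
        isp <- round(t_sp * fs) + 1L
        if (isp <= n) {
          idx <- isp:min(n, isp + length(nm$template) - 1L)
          cpl <- rep_len(nm$coupling, ncol(W))
          for (ch in which(cpl != 0))
            W[idx, ch] <<- W[idx, ch] + cpl[ch] * nm$template[seq_along(idx)]
          truth <<- rbind(truth, data.frame(unit_id = nm$unit_id, time_s = t_sp,
                                            sample = isp, evoked = TRUE))
        }
      }
    }
    invisible()
  }

  codes_now <- numeric(nch)
  for (i in seq_len(n)) {
    t <- (i - 1) * period
    # --- network step at each 0.1 ms boundary
    if (!is.null(net) && t > 0 && t %% snn_step_ticks == 0) {
      r <- step_network(net, snn_st, ext_flags)
      snn_st <- r$state
      ext_flags <- logical(8)
      if (length(r$fired)) {
        io_units <- r$fired[r$fired < 16]
        for (u in io_units)
          snn_records[[length(snn_records) + 1L]] <- data.frame(
            timestamp = t, source = u, kind = "network_event", p1 = 0L, p2 = 0L)
        out_units <- r$fired[r$fired < 8]
        cond <- active_condition(t)
        for (u in out_units) {
          if (u %in% snn_gen_ids) {
            dig_records[[length(dig_records) + 1L]] <- data.frame(
              timestamp = t, source = u, kind = "digital_event", p1 = 0L, p2 = 0L)
            deliver_train(t, t, u, cond)
          }
        }
      }
    }
    # --- acquisition: front-end filters + quantization
    x <- W[i, cols]
    y0 <- hp0 * (s_hp0y + x - s_hp0x); s_hp0x <- x; s_hp0y <- y0
    y1 <- hp1 * (s_hp1y + y0 - s_hp1x); s_hp1x <- y0; s_hp1y <- y1
    y2 <- lb[1] * y1 + s_z1
    s_z1 <- lb[2] * y1 - la[2] * y2 + s_z2
    s_z2 <- lb[3] * y1 - la[3] * y2
    mv <- pmin(pmax(y2 + noise[i, ], -adc$input_range_mv), adc$input_range_mv)
    codes_now <- pmin(pmax(round(mv / adc$lsb_mv), adc$code_min), adc$code_max)
    blanked <- t < settle_until
    if (blanked) codes_now[] <- 0
    codes_out[i, ] <- codes_now
    cond <- active_condition(t)
    # --- interval generators
    for (id in names(interval_ev)) {
      ptr <- interval_ptr[[id]]; evs <- interval_ev[[id]]
      while (ptr <= length(evs) && evs[ptr] <= t) {
        g <- as.integer(id)
        dig_records[[length(dig_records) + 1L]] <- data.frame(
          timestamp = evs[ptr], source = g, kind = "digital_event",
          p1 = 0L, p2 = 0L)
        if (!is.null(net)) ext_flags[g + 1] <- TRUE
        deliver_train(evs[ptr], t, g, cond)
        ptr <- ptr + 1L
      }
      interval_ptr[[id]] <- ptr
    }
    # --- window discriminators
    for (id in names(disc)) {
      d <- disc[[id]]
      cur <- codes_now[match(d$gen$source, chan_ids)]
      spec_d <- d$gen$discriminator
      if (!blanked && !is.na(d$prev)) {
        crossed <- if (spec_d$polarity == "rising")
          d$prev < spec_d$threshold && cur >= spec_d$threshold
        else d$prev > spec_d$threshold && cur <= spec_d$threshold
        if (crossed && t - d$last_accept >= spec_d$dead_time_ticks) {
          d$pending[[length(d$pending) + 1L]] <- list(i0 = i, tick = t, w = 1L)
        }
      }
      d$prev <- if (blanked) NA_real_ else cur
      if (length(d$pending)) {
        keep <- list()
        for (p in d$pending) {
          due <- p$i0 + d$dsamp[p$w]
          if (i < due) { keep[[length(keep) + 1L]] <- p; next }
          win <- spec_d$windows[[p$w]]
          v <- cur
          if (v >= win$amplitude_min && v <= win$amplitude_max) {
            if (p$w == length(spec_d$windows)) {
              if (p$tick - d$last_accept >= spec_d$dead_time_ticks) {
                d$last_accept <- p$tick
                g <- d$gen$gen_id
                dig_records[[length(dig_records) + 1L]] <- data.frame(
                  timestamp = p$tick, source = g, kind = "digital_event",
                  p1 = 0L, p2 = 0L)
                if (!is.null(net)) ext_flags[g + 1] <- TRUE
                deliver_train(p$tick, t, g, cond)
              }
            } else {
              p$w <- p$w + 1L
              keep[[length(keep) + 1L]] <- p
            }
          }
        }
        d$pending <- keep
      }
      disc[[id]] <- d
    }
  }

  # --- assemble records and write the session
  all_rec <- c(dig_records, stim_records, snn_records)
  records <- if (length(all_rec)) do.call(rbind, all_rec) else
    data.frame(timestamp = numeric(), source = integer(), kind = character(),
               p1 = integer(), p2 = integer())
  cond_rec <- seq_out$records
  cond_rec$p1 <- 0L; cond_rec$p2 <- 0L
  records <- rbind(records, cond_rec)
  records <- records[order(records$timestamp, records$source), , drop = FALSE]
  pulses_df <- if (length(pulses)) do.call(rbind, pulses) else empty_pulses()
  rejected_df <- if (length(rejected)) do.call(rbind, rejected) else
    data.frame(trigger_ts = numeric(), source = integer(), reason = character())

  blocks <- list()
  block_n <- max(1L, round(block_s * fs))
  for (j in seq_len(nch)) {
    for (s0 in seq(1L, n, by = block_n)) {
      s1 <- min(n, s0 + block_n - 1L)
      blocks[[length(blocks) + 1L]] <- analog_block(
        chan_ids[j], (s0 - 1) * period, period, codes_out[s0:s1, j])
    }
  }
  hdr <- session_header(config, 0, chan_ids)
  write_session(path, hdr, blocks, records)

  truth <- truth[order(truth$time_s), , drop = FALSE]
  list(path = path, pulses = pulses_df, rejected = rejected_df,
       records = records, truth = truth, codes = codes_out,
       blanking = if (length(blank_iv)) do.call(rbind, blank_iv) else
         matrix(numeric(), 0, 2),
       summary = list(
         n_digital = sum(records$kind == "digital_event"),
         n_stim = sum(records$kind == "stimulus_event"),
         n_network = sum(records$kind == "network_event"),
         n_rejected = nrow(rejected_df)))
}
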