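# 6-channel constant-current stimulator emulation. All output channels share
# one programmable current source, so pulses can never overlap: overlapping
# requests are interleaved, with a 0.4 ms switching time between pulses on
# different pin pairs. A global refractory period keeps pulse-train onsets
# apart across all channels, and a sliding-window rate cap bounds sustained
# pulse rates (350/s at +/-60 V full-amplitude trains, 700/s at +/-50 V,
# 500/s otherwise).

AMP_RANGE_UA <- c(5, 10000)      # 5 uA - 10 mA
WIDTH_RANGE_MS <- c(0.01, 10)    # per phase

#' Biphasic stimulus waveform
#'
#' A waveform is defined by its delay from the trigger, two phases
#' (amplitude and width each, opposite signs; asymmetric phases allowed), a
#' pulse count per trigger, the inter-pulse interval (0 selects back-to-back
#' burst mode) and the output pins (a differential anodal/cathodal pair or a
#' single-ended pin).
#'
#' @param waveform_id Waveform index 0--5 within its condition.
#' @param delay_ticks Trigger-to-first-pulse delay in ticks.
#' @param amp1_ua,width1_ticks First-phase amplitude (uA, signed) and width.
#' @param amp2_ua,width2_ticks Second phase; sign must oppose phase 1.
#' @param count Pulses per trigger.
#' @param ipi_ticks Inter-pulse interval between pulse onsets; 0 = burst
#'   mode (pulses follow back-to-back with no gap).
#' @param pins `c(anodal, cathodal)` pin pair (0--5, distinct), or a single
#'   pin for single-ended output.
#' @return An object of class `"stim_waveform"`.
#' @export
stim_waveform <- function(waveform_id, delay_ticks = 0,
                          amp1_ua, width1_ticks, amp2_ua, width2_ticks,
                          count = 1L, ipi_ticks = 0, pins = c(0L, 1L)) {
  structure(list(waveform_id = as.integer(waveform_id),
                 delay_ticks = delay_ticks,
                 amp1_ua = amp1_ua, width1_ticks = width1_ticks,
                 amp2_ua = amp2_ua, width2_ticks = width2_ticks,
                 count = as.integer(count), ipi_ticks = ipi_ticks,
                 pins = as.integer(pins)),
            class = "stim_waveform")
}

#' Validate a stimulus waveform
#'
#' Checks the hardware ranges: phase amplitudes within 5 uA--10 mA
#' (magnitude), phase widths within 0.01--10 ms, opposite phase signs,
#' positive count, valid distinct pins.
#'
#' @param w A [stim_waveform()].
#' @param tb A [timebase()].
#' @return `w`, invisibly, if valid; otherwise an error naming the field.
#' @export
validate_waveform <- function(w, tb = timebase()) {
  stopifnot(inherits(w, "stim_waveform"))
  amps <- abs(c(w$amp1_ua, w$amp2_ua))
  if (any(amps < AMP_RANGE_UA[1]) || any(amps > AMP_RANGE_UA[2]))
    stop("amplitude out of range (field amp: ", paste(amps, collapse = "/"),
         " uA, allowed 5 uA-10 mA)", call. = FALSE)
  widths_ms <- ticks_to_ms(c(w$width1_ticks, w$width2_ticks), tb)
  if (any(widths_ms < WIDTH_RANGE_MS[1]) || any(widths_ms > WIDTH_RANGE_MS[2]))
    stop("phase width out of range (field width: ",
         paste(widths_ms, collapse = "/"), " ms, allowed 0.01-10 ms)",
         call. = FALSE)
  if (sign(w$amp1_ua) == sign(w$amp2_ua))
    stop("biphasic phases must have opposite signs (field amp)", call. = FALSE)
  if (w$count < 1L) stop("count must be >= 1 (field count)", call. = FALSE)
  if (w$ipi_ticks < 0) stop("ipi_ticks must be >= 0 (field ipi)", call. = FALSE)
  if (!length(w$pins) %in% 1:2 || any(w$pins < 0 | w$pins > 5))
    stop("pins must be 1 or 2 values in 0-5 (field pins)", call. = FALSE)
  if (length(w$pins) == 2L && w$pins[1] == w$pins[2])
    stop("anodal and cathodal pins must differ (field pins)", call. = FALSE)
  invisible(w)
}

#' Stimulation condition
#'
#' One of up to eight conditions; each specifies its own waveforms (up to
#' six) and which event generators trigger which waveforms, optionally gated
#' by [gate_rule()]s.
#'
#' @param condition_id Condition index 0--7.
#' @param waveforms List of [stim_waveform()]s (<= 6).
#' @param trigger_map List of mappings, each
#'   `list(gen =, waveform_ids =, rules = list())`: events from generator
#'   `gen` trigger the listed waveforms when all rules pass.
#' @param duration_ticks Time-based condition duration; `NULL` = until the
#'   end of the session.
#' @return An object of class `"stim_condition"`.
#' @export
stim_condition <- function(condition_id, waveforms = list(),
                           trigger_map = list(), duration_ticks = NULL) {
  if (condition_id < 0 || condition_id > 7)
    stop("condition_id must be 0-7", call. = FALSE)
  if (length(waveforms) > 6L)
    stop("at most 6 waveforms per condition", call. = FALSE)
  wf_ids <- vapply(waveforms, `[[`, 0L, "waveform_id")
  for (m in trigger_map)
    if (!all(m$waveform_ids %in% wf_ids))
      stop("trigger_map references unknown waveform ids", call. = FALSE)
  structure(list(condition_id = as.integer(condition_id),
                 waveforms = waveforms, trigger_map = trigger_map,
                 duration_ticks = duration_ticks),
            class = "stim_condition")
}

#' Scheduler state
#'
#' Mutable bookkeeping of the shared current source: when it frees up, which
#' pins it last drove, the refractory horizon, and the sliding one-second
#' log of delivered pulses used to enforce the rate cap.
#'
#' @param refractory_ms Global refractory between accepted pulse-train
#'   onsets, across all channels (default 10 ms; 0 disables).
#' @param compliance_v 60 (full-amplitude cap 350/s) or 50 (cap 700/s).
#' @param switch_ms Source switching time between pulses on different pin
#'   pairs (default 0.4 ms).
#' @param tb A [timebase()].
#' @return An object of class `"scheduler_state"`.
#' @export
scheduler_state <- function(refractory_ms = 10, compliance_v = 60,
                            switch_ms = 0.4, tb = timebase()) {
  structure(list(
    refractory_ticks = ms_to_ticks(refractory_ms, tb),
    compliance_v = compliance_v,
    switch_ticks = ms_to_ticks(switch_ms, tb),
    second_ticks = s_to_ticks(1, tb),
    busy_until = -Inf, last_pins = NULL,
    refractory_until = -Inf,
    pulse_log = numeric(0),        # delivered pulse onsets (sliding window)
    accepted_triggers = numeric(0)
  ), class = "scheduler_state")
}

# sustained-rate cap for a waveform: full-amplitude (>= 1 mA) trains are
# limited by the compliance voltage (350/s at 60 V, 700/s at 50 V); normal
# amplitudes by the 500/s overall limit
rate_cap_for <- function(w, compliance_v) {
  if (max(abs(c(w$amp1_ua, w$amp2_ua))) >= 1000)
    if (compliance_v >= 60) 350 else 700
  else 500
}

#' Schedule stimulus pulses from triggers
#'
#' Converts accepted trigger events into concrete pulses on the shared
#' current source. For each trigger, each mapped waveform requests `count`
#' pulses starting at `trigger + delay`, spaced by the inter-pulse interval
#' (back-to-back when it is 0). Requests that would overlap are interleaved
#' in first-come order (ties broken by ascending waveform id): a pulse on a
#' different pin pair starts no earlier than the previous pulse's end plus
#' the switching time; same-pin pulses may follow immediately. Triggers
#' whose train onset falls inside the global refractory window
#' `[previous onset, previous onset + refractory)` are dropped, as are
#' triggers that would push the sliding one-second delivered-pulse count
#' over the rate cap. Drops are logged, never raised.
#'
#' @param triggers [event_records()] of candidate triggers, sorted.
#' @param condition A validated [stim_condition()].
#' @param state A [scheduler_state()].
#' @param level_values Current analog values for level gate rules.
#' @return List with `pulses` (data frame: onset, end, per-phase amplitudes
#'   and widths, pins, waveform_id, trigger_ts), `rejected` (data frame:
#'   trigger_ts, source, reason) and the updated `state`.
#' @export
schedule_pulses <- function(triggers, condition, state = scheduler_state(),
                            level_values = list()) {
  stopifnot(inherits(condition, "stim_condition"))
  wf_by_id <- stats::setNames(condition$waveforms,
                              vapply(condition$waveforms, `[[`, 0L, "waveform_id"))
  pulses <- list(); rejected <- list()
  for (i in seq_len(nrow(triggers))) {
    trg <- triggers$timestamp[i]; src <- triggers$source[i]
    maps <- Filter(function(m) m$gen == src, condition$trigger_map)
    if (!length(maps)) next
    wf_ids <- sort(unique(unlist(lapply(maps, `[[`, "waveform_ids"))))
    rules <- unlist(lapply(maps, `[[`, "rules"), recursive = FALSE)
    g <- gate_trigger(trg, rules %||% list(), state$accepted_triggers, level_values)
    if (!g$accept) {
      rejected[[length(rejected) + 1L]] <-
        data.frame(trigger_ts = trg, source = src, reason = g$reason)
      next
    }
    ws <- wf_by_id[as.character(wf_ids)]
    train_onset <- min(vapply(ws, function(w) trg + w$delay_ticks, 0))
    if (train_onset < state$refractory_until) {
      rejected[[length(rejected) + 1L]] <-
        data.frame(trigger_ts = trg, source = src, reason = "refractory")
      next
    }
    n_train <- sum(vapply(ws, `[[`, 0L, "count"))
    cap <- min(vapply(ws, rate_cap_for, 0, compliance_v = state$compliance_v))
    in_window <- sum(state$pulse_log > train_onset - state$second_ticks &
                     state$pulse_log <= train_onset)
    if (in_window + n_train > cap) {
      rejected[[length(rejected) + 1L]] <-
        data.frame(trigger_ts = trg, source = src, reason = "rate_cap")
      next
    }
    # build the request list for this trigger and serialize on the source
    req <- do.call(rbind, lapply(ws, function(w) {
      width <- w$width1_ticks + w$width2_ticks
      step <- if (w$ipi_ticks > 0) w$ipi_ticks else width
      data.frame(requested = trg + w$delay_ticks + (seq_len(w$count) - 1L) * step,
                 waveform_id = w$waveform_id)
    }))
    req <- req[order(req$requested, req$waveform_id), , drop = FALSE]
    for (k in seq_len(nrow(req))) {
      w <- wf_by_id[[as.character(req$waveform_id[k])]]
      pins <- if (length(w$pins) == 2L) w$pins else c(w$pins, NA_integer_)
      earliest <- if (!is.null(state$last_pins) && identical(state$last_pins, pins))
        state$busy_until
      else if (is.finite(state$busy_until))
        state$busy_until + state$switch_ticks
      else -Inf
      onset <- max(req$requested[k], earliest)
      end <- onset + w$width1_ticks + w$width2_ticks
      pulses[[length(pulses) + 1L]] <- data.frame(
        onset = onset, end = end,
        amp1_ua = w$amp1_ua, width1_ticks = w$width1_ticks,
        amp2_ua = w$amp2_ua, width2_ticks = w$width2_ticks,
        pin_a = pins[1], pin_c = pins[2],
        waveform_id = w$waveform_id, trigger_ts = trg)
      state$busy_until <- end
      state$last_pins <- pins
      state$pulse_log <- c(state$pulse_log, onset)
    }
    if (state$refractory_ticks > 0)
      state$refractory_until <- train_onset + state$refractory_ticks
    state$accepted_triggers <- c(state$accepted_triggers, trg)
    # trim the sliding log to what any future window can see
    if (length(state$pulse_log) > 4096L) {
      keep <- state$pulse_log > max(state$pulse_log) - state$second_ticks
      state$pulse_log <- state$pulse_log[keep]
    }
  }
  list(pulses = if (length(pulses)) do.call(rbind, pulses) else empty_pulses(),
       rejected = if (length(rejected)) do.call(rbind, rejected) else
         data.frame(trigger_ts = numeric(), source = integer(), reason = character()),
       state = state)
}

empty_pulses <- function() {
  data.frame(onset = numeric(), end = numeric(), amp1_ua = numeric(),
             width1_ticks = numeric(), amp2_ua = numeric(),
             width2_ticks = numeric(), pin_a = integer(), pin_c = integer(),
             waveform_id = integer(), trigger_ts = numeric())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sequence stimulation conditions over a session
#'
#' Exactly one condition is active at any tick. Conditions advance on their
#' configured time-based durations; a condition without a duration runs to
#' the end of the session. Each transition (including the initial one at
#' tick 0) emits a condition-change record.
#'
#' @param conditions List of [stim_condition()]s (>= 1, <= 8).
#' @param duration_ticks Session length.
#' @return List with `segments` (data frame: condition_id, start, end) and
#'   `records` ([event_records()] of kind `"condition_transition"`).
#' @export
sequence_conditions <- function(conditions, duration_ticks) {
  if (!length(conditions)) stop("at least one condition required", call. = FALSE)
  if (length(conditions) > 8L) stop("at most 8 conditions", call. = FALSE)
  start <- 0; segs <- list()
  for (i in seq_along(conditions)) {
    cond <- conditions[[i]]
    end <- if (is.null(cond$duration_ticks) || i == length(conditions))
      duration_ticks else min(duration_ticks, start + cond$duration_ticks)
    segs[[i]] <- data.frame(condition_id = cond$condition_id,
                            start = start, end = end)
    start <- end
    if (start >= duration_ticks) break
  }
  segs <- do.call(rbind, segs)
  list(segments = segs,
       records = event_records(segs$start, segs$condition_id,
                               "condition_transition"))
}

#' Render the stimulator monitor trace
#'
#' The monitor channel records the voltage the constant-current source
#' develops across the load: `V(t) = I(t) * R`, clipped at the compliance
#' voltage. Each pulse is flagged when its demanded voltage exceeds
#' compliance (the commanded current can then no longer be delivered).
#'
#' @param pulses Pulse data frame from [schedule_pulses()].
#' @param load_ohms Load resistance (> 0).
#' @param compliance_v Compliance voltage (default 60).
#' @param fs Monitor sample rate in Sps.
#' @param duration_ticks Trace length in ticks.
#' @param tb A [timebase()].
#' @return List with `voltage` (V, one sample per monitor period) and
#'   `limited` (logical per pulse: compliance-limited).
#' @export
render_monitor_trace <- function(pulses, load_ohms, compliance_v = 60,
                                 fs = 20000, duration_ticks = NULL,
                                 tb = timebase()) {
  if (load_ohms <= 0) stop("load_ohms must be positive", call. = FALSE)
  period <- sample_period_ticks(fs, tb)
  if (is.null(duration_ticks))
    duration_ticks <- if (nrow(pulses)) max(pulses$end) + period else period
  n <- ceiling(duration_ticks / period)
  v <- numeric(n)
  limited <- logical(nrow(pulses))
  t_ticks <- (seq_len(n) - 1) * period
  for (k in seq_len(nrow(pulses))) {
    p <- pulses[k, ]
    v1 <- p$amp1_ua * 1e-6 * load_ohms
    v2 <- p$amp2_ua * 1e-6 * load_ohms
    limited[k] <- max(abs(c(v1, v2))) > compliance_v
    i1 <- t_ticks >= p$onset & t_ticks < p$onset + p$width1_ticks
    i2 <- t_ticks >= p$onset + p$width1_ticks & t_ticks < p$end
    v[i1] <- v1; v[i2] <- v2
  }
  v <- pmin(pmax(v, -compliance_v), compliance_v)
  list(voltage = v, limited = limited)
}
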