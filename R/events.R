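# Firmware event generators: interval-based event emission (fixed, uniform
# or exponential gaps), dual time-amplitude window spike discrimination on a
# sampled channel, and trigger gating rules (event counts in a lookback
# window, analog level inside/outside a band).

#' Timestamped event records
#'
#' All discrete occurrences in a session -- generator ticks, discriminator
#' hits, stimulus deliveries, condition transitions, network spikes -- are
#' kept as rows of a data frame totally ordered by `(timestamp, source)`.
#'
#' @param timestamp Tick timestamps (non-negative).
#' @param source Integer source id (generator, stim channel, condition or
#'   network unit, depending on `kind`).
#' @param kind Event class tag, e.g. `"digital_event"`, `"stimulus_event"`,
#'   `"condition_transition"`, `"network_event"`.
#' @return A data frame with columns `timestamp`, `source`, `kind`, sorted.
#' @export
event_records <- function(timestamp = numeric(), source = integer(),
                          kind = character()) {
  if (length(timestamp) && any(timestamp < 0))
    stop("event timestamps must be non-negative", call. = FALSE)
  df <- data.frame(timestamp = as.numeric(timestamp),
                   source = as.integer(rep_len(source, length(timestamp))),
                   kind = as.character(rep_len(kind, length(timestamp))))
  df[order(df$timestamp, df$source), , drop = FALSE]
}

#' Dual time-amplitude window discriminator specification
#'
#' A spike is accepted when the sampled signal crosses a threshold with the
#' stated polarity and the samples at one or two fixed delays after the
#' crossing fall inside user-defined amplitude windows (closed intervals).
#' Accepted events are separated by at least `dead_time_ticks`.
#'
#' @param threshold Threshold in code units.
#' @param polarity `"rising"` or `"falling"` crossing.
#' @param windows List of windows, each
#'   `list(delay_ticks =, amplitude_min =, amplitude_max =)`; one or two,
#'   with strictly increasing delays.
#' @param dead_time_ticks Minimum separation between accepted events
#'   (default 1 ms worth of ticks).
#' @return An object of class `"window_disc_spec"`.
#' @export
window_disc_spec <- function(threshold, polarity = c("rising", "falling"),
                             windows, dead_time_ticks = 100) {
  polarity <- match.arg(polarity)
  if (!length(windows) %in% 1:2) stop("1 or 2 windows required", call. = FALSE)
  delays <- vapply(windows, `[[`, 0, "delay_ticks")
  if (is.unsorted(delays, strictly = TRUE))
    stop("window delays must be strictly increasing", call. = FALSE)
  for (w in windows)
    if (w$amplitude_min > w$amplitude_max)
      stop("window amplitude_min must be <= amplitude_max", call. = FALSE)
  if (dead_time_ticks < 0) stop("dead_time_ticks must be >= 0", call. = FALSE)
  structure(list(threshold = threshold, polarity = polarity,
                 windows = windows, dead_time_ticks = dead_time_ticks),
            class = "window_disc_spec")
}

#' Event generator specification
#'
#' One of the eight firmware event generators. Interval modes emit events at
#' fixed or random (uniform or exponential) gaps; discriminator mode runs a
#' [window_disc_spec()] on a source channel or filter-bank slot; network
#' mode is activated by output spikes of the on-board network.
#'
#' @param gen_id Generator index 0--7.
#' @param mode One of `"fixed_interval"`, `"uniform_interval"`,
#'   `"exponential_interval"`, `"window_discriminator"`, `"snn_output"`.
#' @param period_ticks Gap for fixed mode.
#' @param range_ticks `c(lo, hi)` gap bounds for uniform mode.
#' @param mean_ticks Mean gap for exponential mode.
#' @param source Source channel id (or `list(slot = k)` for a bank slot) in
#'   discriminator mode.
#' @param discriminator A [window_disc_spec()] in discriminator mode.
#' @param gate_rules Optional list of [gate_rule()]s applied to this
#'   generator's events when they are used as stimulus triggers.
#' @return An object of class `"event_generator"`.
#' @export
event_generator <- function(gen_id,
                            mode = c("fixed_interval", "uniform_interval",
                                     "exponential_interval",
                                     "window_discriminator", "snn_output"),
                            period_ticks = NULL, range_ticks = NULL,
                            mean_ticks = NULL, source = NULL,
                            discriminator = NULL, gate_rules = list()) {
  mode <- match.arg(mode)
  if (gen_id < 0 || gen_id > 7) stop("gen_id must be 0-7", call. = FALSE)
  chk_pos <- function(x, nm)
    if (is.null(x) || any(x <= 0))
      stop("generator ", gen_id, ": ", nm, " must be positive", call. = FALSE)
  switch(mode,
    fixed_interval = chk_pos(period_ticks, "period_ticks"),
    uniform_interval = {
      chk_pos(range_ticks, "range_ticks")
      if (length(range_ticks) != 2L || range_ticks[1] > range_ticks[2])
        stop("range_ticks must be c(lo, hi) with lo <= hi", call. = FALSE)
    },
    exponential_interval = chk_pos(mean_ticks, "mean_ticks"),
    window_discriminator = {
      if (is.null(source) || is.null(discriminator))
        stop("discriminator mode needs source and discriminator", call. = FALSE)
      stopifnot(inherits(discriminator, "window_disc_spec"))
    },
    snn_output = NULL)
  structure(list(gen_id = as.integer(gen_id), mode = mode,
                 period_ticks = period_ticks, range_ticks = range_ticks,
                 mean_ticks = mean_ticks, source = source,
                 discriminator = discriminator, gate_rules = gate_rules),
            class = "event_generator")
}

#' Generate interval-mode events
#'
#' Fixed mode emits events at exact multiples of the period; uniform and
#' exponential modes draw successive gaps i.i.d. from the stated
#' distribution. Gaps are rounded to whole ticks and the first event occurs
#' one gap after time zero.
#'
#' @param spec An interval-mode [event_generator()].
#' @param duration_ticks Session duration in ticks.
#' @param stream An [rng_stream()] (required for the random modes).
#' @return [event_records()] of kind `"digital_event"`.
#' @export
generate_interval_events <- function(spec, duration_ticks, stream = NULL) {
  stopifnot(inherits(spec, "event_generator"))
  ts <- switch(spec$mode,
    fixed_interval = {
      p <- spec$period_ticks
      if (duration_ticks >= p) seq(p, duration_ticks, by = p) else numeric()
    },
    uniform_interval = ,
    exponential_interval = {
      if (is.null(stream)) stop("random interval mode needs an rng_stream", call. = FALSE)
      mean_gap <- if (spec$mode == "uniform_interval")
        mean(spec$range_ticks) else spec$mean_ticks
      out <- numeric(0); t <- 0
      repeat {
        n_guess <- max(16L, ceiling(1.5 * (duration_ticks - t) / mean_gap))
        gaps <- if (spec$mode == "uniform_interval")
          round(stream_runif(stream, n_guess, spec$range_ticks[1], spec$range_ticks[2]))
        else
          round(stream_rexp(stream, n_guess, rate = 1 / spec$mean_ticks))
        tt <- t + cumsum(gaps)
        out <- c(out, tt[tt <= duration_ticks])
        t <- tt[length(tt)]
        if (t > duration_ticks) break
      }
      out
    },
    stop("not an interval-mode generator: ", spec$mode, call. = FALSE))
  event_records(ts, spec$gen_id, "digital_event")
}

#' Dual time-amplitude window spike discrimination
#'
#' Scans a sampled trace for threshold crossings of the configured polarity
#' and accepts a crossing as a spike only if, for every configured window,
#' the sample at `crossing + delay` lies within its closed amplitude band.
#' Crossings within the dead time of a previously accepted event, or within
#' a blanking interval, are ignored. The event is timestamped at the
#' crossing sample.
#'
#' @param codes Sampled trace (code units); sample `i` at tick
#'   `(i-1) * period`.
#' @param sample_rate Trace sample rate in Sps.
#' @param spec A [window_disc_spec()]; window delays must be whole samples
#'   at this rate.
#' @param blanking Optional two-column matrix of `[start, end)` tick
#'   intervals to ignore (e.g. from [apply_fast_settle()]).
#' @param gen_id Source generator id recorded in the output.
#' @param tb A [timebase()].
#' @return [event_records()] of kind `"digital_event"`.
#' @export
discriminate_spikes <- function(codes, sample_rate, spec, blanking = NULL,
                                gen_id = 0L, tb = timebase()) {
  stopifnot(inherits(spec, "window_disc_spec"))
  period <- sample_period_ticks(sample_rate, tb)
  delays <- vapply(spec$windows, `[[`, 0, "delay_ticks")
  if (any(delays %% period != 0))
    stop("window delay not a multiple of the sample period (", period,
         " ticks)", call. = FALSE)
  dsamp <- delays %/% period
  n <- length(codes)
  if (n < 2L) return(event_records())
  thr <- spec$threshold
  prev <- codes[-n]; cur <- codes[-1L]
  cross <- if (spec$polarity == "rising")
    which(prev < thr & cur >= thr) + 1L
  else
    which(prev > thr & cur <= thr) + 1L
  t_ticks <- (cross - 1) * period
  if (!is.null(blanking) && nrow(blanking) && length(cross)) {
    keep <- rep(TRUE, length(cross))
    for (k in seq_len(nrow(blanking)))
      keep <- keep & !(t_ticks >= blanking[k, 1] & t_ticks < blanking[k, 2])
    cross <- cross[keep]; t_ticks <- t_ticks[keep]
  }
  accepted <- numeric(0)
  last <- -Inf
  for (j in seq_along(cross)) {
    i <- cross[j]; t <- t_ticks[j]
    if (t - last < spec$dead_time_ticks) next
    ok <- TRUE
    for (w in seq_along(spec$windows)) {
      k <- i + dsamp[w]
      if (k > n) { ok <- FALSE; break }
      v <- codes[k]
      win <- spec$windows[[w]]
      if (v < win$amplitude_min || v > win$amplitude_max) { ok <- FALSE; break }
    }
    if (ok) { accepted <- c(accepted, t); last <- t }
  }
  event_records(accepted, gen_id, "digital_event")
}

#' Trigger gating rule
#'
#' Potential stimulus triggers may be rejected when event occurrences or
#' source analog levels meet configured requirements: the count of prior
#' events in a lookback window, or the current source value falling inside
#' or outside an amplitude band.
#'
#' @param kind `"count_in_window"`, `"level_inside"` or `"level_outside"`.
#' @param max_events,min_events For count rules: accept only if the count of
#'   history events in `(t - lookback, t]` is `<= max_events` (resp.
#'   `>= min_events`). Supply exactly one of the two.
#' @param lookback_ticks Lookback window length (count rules; must be > 0).
#' @param source Level-rule source id (informational).
#' @param min,max Level band bounds (closed interval).
#' @return An object of class `"gate_rule"`.
#' @export
gate_rule <- function(kind = c("count_in_window", "level_inside", "level_outside"),
                      max_events = NULL, min_events = NULL,
                      lookback_ticks = NULL, source = NULL,
                      min = NULL, max = NULL) {
  kind <- match.arg(kind)
  if (kind == "count_in_window") {
    if (is.null(lookback_ticks) || lookback_ticks <= 0)
      stop("count rule needs lookback_ticks > 0", call. = FALSE)
    if (is.null(max_events) == is.null(min_events))
      stop("count rule needs exactly one of max_events / min_events", call. = FALSE)
  } else if (is.null(min) || is.null(max)) {
    stop("level rule needs min and max", call. = FALSE)
  }
  structure(list(kind = kind, max_events = max_events, min_events = min_events,
                 lookback_ticks = lookback_ticks, source = source,
                 min = min, max = max), class = "gate_rule")
}

#' Gate a candidate trigger
#'
#' A candidate is accepted iff every rule passes. Count rules count history
#' events in the half-open lookback window `(t - lookback, t]`; level rules
#' test the current source value against the closed band. An empty rule list
#' accepts.
#'
#' @param candidate_ts Candidate timestamp (ticks).
#' @param rules List of [gate_rule()]s.
#' @param history_ts Timestamps of prior events (sorted ascending).
#' @param level_values Named list/vector of current analog values by source
#'   id, consulted by level rules.
#' @return List with `accept` (logical) and `reason` (`NA` or the failing
#'   rule's description).
#' @export
gate_trigger <- function(candidate_ts, rules, history_ts = numeric(),
                         level_values = list()) {
  for (r in rules) {
    if (r$kind == "count_in_window") {
      cnt <- sum(history_ts > candidate_ts - r$lookback_ticks &
                 history_ts <= candidate_ts)
      if (!is.null(r$max_events) && cnt > r$max_events)
        return(list(accept = FALSE,
                    reason = sprintf("count %d > max %d in lookback", cnt, r$max_events)))
      if (!is.null(r$min_events) && cnt < r$min_events)
        return(list(accept = FALSE,
                    reason = sprintf("count %d < min %d in lookback", cnt, r$min_events)))
    } else {
      v <- level_values[[as.character(r$source)]]
      if (is.null(v)) return(list(accept = FALSE, reason = "level source unavailable"))
      inside <- v >= r$min && v <= r$max
      if (r$kind == "level_inside" && !inside)
        return(list(accept = FALSE, reason = "level outside required band"))
      if (r$kind == "level_outside" && inside)
        return(list(accept = FALSE, reason = "level inside rejected band"))
    }
  }
  list(accept = TRUE, reason = NA_character_)
}
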