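test_that("waveform validation enforces hardware ranges", {
  expect_silent(validate_waveform(canonical_waveform()))   # 1 mA, 0.2 ms/phase
  w <- canonical_waveform(amp_ua = 4)
  expect_error(validate_waveform(w), "amplitude")
  w <- stim_waveform(0, 0, 100, ms_to_ticks(11), -100, 20)
  expect_error(validate_waveform(w), "width")
  w <- stim_waveform(0, 0, 100, 20, 100, 20)               # same-sign phases
  expect_error(validate_waveform(w), "opposite")
  w <- stim_waveform(0, 0, 100, 20, -100, 20, pins = c(2, 2))
  expect_error(validate_waveform(w), "pins")
})

test_that("trains follow delay, count and inter-pulse interval arithmetic", {
  w <- canonical_waveform(delay_ticks = ms_to_ticks(1), count = 3,
                          ipi_ticks = ms_to_ticks(5), amp_ua = 100)
  cond <- one_waveform_condition(w)
  st <- scheduler_state(refractory_ms = 0)
  r <- schedule_pulses(event_records(0, 0, "digital_event"), cond, st)
  expect_equal(r$pulses$onset, ms_to_ticks(c(1, 6, 11)))
})

test_that("interleaved waveforms are 0.8 ms apart leading edge to leading edge", {
  w0 <- canonical_waveform(0, pins = c(0L, 1L))
  w1 <- canonical_waveform(1, pins = c(2L, 3L))
  cond <- stim_condition(0, list(w0, w1),
                         list(list(gen = 0, waveform_ids = c(0L, 1L),
                                   rules = list())))
  r <- schedule_pulses(event_records(0, 0, "digital_event"), cond,
                       scheduler_state(refractory_ms = 0))
  expect_equal(nrow(r$pulses), 2)
  expect_equal(diff(r$pulses$onset), ms_to_ticks(0.8))
})

test_that("burst mode delivers 20 back-to-back pulses within 2 ms", {
  w <- stim_waveform(0, 0, amp1_ua = 500, width1_ticks = us_to_ticks(50),
                     amp2_ua = -500, width2_ticks = us_to_ticks(50),
                     count = 20L, ipi_ticks = 0)
  r <- schedule_pulses(event_records(0, 0, "digital_event"),
                       one_waveform_condition(w),
                       scheduler_state(refractory_ms = 0))
  expect_equal(nrow(r$pulses), 20)
  expect_equal(diff(r$pulses$onset), rep(us_to_ticks(100), 19))  # no gaps
  expect_lte(max(r$pulses$end) - min(r$pulses$onset), ms_to_ticks(2))
})

test_that("the global refractory drops trains inside its half-open window", {
  w <- canonical_waveform(amp_ua = 100)
  cond <- one_waveform_condition(w)
  trg <- event_records(ms_to_ticks(c(0, 5, 12)), 0, "digital_event")
  r <- schedule_pulses(trg, cond, scheduler_state(refractory_ms = 10))
  expect_equal(r$pulses$onset, ms_to_ticks(c(0, 12)))
  expect_equal(r$rejected$reason, "refractory")
  # a trigger at exactly onset + 10 ms is accepted
  trg2 <- event_records(ms_to_ticks(c(0, 10)), 0, "digital_event")
  r2 <- schedule_pulses(trg2, cond, scheduler_state(refractory_ms = 10))
  expect_equal(nrow(r2$pulses), 2)
})

test_that("the sliding-window rate cap drops excess triggers", {
  w <- canonical_waveform(amp_ua = 100)          # normal amplitude: 500/s cap
  cond <- one_waveform_condition(w)
  trg <- event_records(ms_to_ticks(0:999), 0, "digital_event")
  r <- schedule_pulses(trg, cond, scheduler_state(refractory_ms = 0))
  expect_equal(nrow(r$pulses), 500)
  expect_true(all(r$rejected$reason == "rate_cap"))
  # full-amplitude trains at +/-60 V are capped at 350/s, 700/s at +/-50 V
  wf <- canonical_waveform(amp_ua = 1000)
  condf <- one_waveform_condition(wf)
  r60 <- schedule_pulses(trg, condf,
                         scheduler_state(refractory_ms = 0, compliance_v = 60))
  expect_equal(nrow(r60$pulses), 350)
  r50 <- schedule_pulses(trg, condf,
                         scheduler_state(refractory_ms = 0, compliance_v = 50))
  expect_equal(nrow(r50$pulses), 700)
})

test_that("symmetric biphasic trains carry zero net charge", {
  for (amp in c(50, 500, 5000)) {
    w <- canonical_waveform(amp_ua = amp, count = 5L,
                            ipi_ticks = ms_to_ticks(3))
    r <- schedule_pulses(event_records(0, 0, "digital_event"),
                         one_waveform_condition(w),
                         scheduler_state(refractory_ms = 0))
    charge <- with(r$pulses, sum(amp1_ua * width1_ticks + amp2_ua * width2_ticks))
    expect_equal(charge, 0)
  }
})

test_that("the shared source never drives two pulses at once", {
  set.seed(42)
  wfs <- list(canonical_waveform(0, pins = c(0L, 1L), amp_ua = 100),
              canonical_waveform(1, pins = c(2L, 3L), amp_ua = 200,
                                 count = 2L, ipi_ticks = ms_to_ticks(1)),
              canonical_waveform(2, pins = c(4L, 5L), amp_ua = 300))
  cond <- stim_condition(0, wfs,
                         list(list(gen = 0, waveform_ids = 0L, rules = list()),
                              list(gen = 1, waveform_ids = 1L, rules = list()),
                              list(gen = 2, waveform_ids = 2L, rules = list())))
  trg <- event_records(sort(sample(0:s_to_ticks(0.5), 60)),
                       sample(0:2, 60, replace = TRUE), "digital_event")
  r <- schedule_pulses(trg, cond, scheduler_state(refractory_ms = 0))
  p <- r$pulses[order(r$pulses$onset), ]
  expect_true(all(p$onset[-1] >= p$end[-nrow(p)]))      # no overlap
  # different pin pairs additionally separated by the switching time
  diff_pins <- p$pin_a[-1] != p$pin_a[-nrow(p)]
  gap <- p$onset[-1] - p$end[-nrow(p)]
  expect_true(all(gap[diff_pins] >= ms_to_ticks(0.4)))
})

test_that("single-waveform scheduling matches a tick-walk oracle", {
  w <- canonical_waveform(amp_ua = 100, delay_ticks = 30)
  cond <- one_waveform_condition(w)
  width <- w$width1_ticks + w$width2_ticks
  for (seed in 1:4) {
    set.seed(seed)
    trg_ts <- sort(sample(0:s_to_ticks(0.2), 40))
    refr <- ms_to_ticks(10)
    # oracle: walk triggers in order, tracking refractory and source business
    onsets <- numeric(0); refr_until <- -Inf; busy <- -Inf
    for (t in trg_ts) {
      on <- t + 30
      if (on < refr_until) next
      on <- max(on, busy)      # same pins, no switch gap
      onsets <- c(onsets, on)
      busy <- on + width
      refr_until <- (t + 30) + refr
    }
    r <- schedule_pulses(event_records(trg_ts, 0, "digital_event"), cond,
                         scheduler_state(refractory_ms = 10))
    expect_equal(r$pulses$onset, onsets, info = paste("seed", seed))
  }
})

test_that("condition sequencing keeps exactly one condition active", {
  c0 <- stim_condition(0, duration_ticks = s_to_ticks(60))
  c1 <- stim_condition(1)
  r <- sequence_conditions(list(c0, c1), s_to_ticks(120))
  expect_equal(nrow(r$segments), 2)
  expect_equal(r$segments$end[1], s_to_ticks(60))
  expect_equal(r$records$timestamp, c(0, s_to_ticks(60)))
  expect_equal(r$segments$start[-1], r$segments$end[-2])   # no gap, no overlap
  single <- sequence_conditions(list(c1), s_to_ticks(10))
  expect_equal(nrow(single$records), 1)
  expect_error(sequence_conditions(list(), 100), "at least one")
})

test_that("the monitor trace obeys Ohm's law and compliance clipping", {
  w <- canonical_waveform(amp_ua = 1000)
  r <- schedule_pulses(event_records(0, 0, "digital_event"),
                       one_waveform_condition(w),
                       scheduler_state(refractory_ms = 0))
  m <- render_monitor_trace(r$pulses, load_ohms = 10000)
  expect_equal(max(m$voltage), 10)               # 1 mA x 10 kOhm
  expect_false(any(m$limited))
  w2 <- canonical_waveform(amp_ua = 2000)
  r2 <- schedule_pulses(event_records(0, 0, "digital_event"),
                        one_waveform_condition(w2),
                        scheduler_state(refractory_ms = 0))
  m2 <- render_monitor_trace(r2$pulses, load_ohms = 40000)
  expect_equal(max(abs(m2$voltage)), 60)         # clipped at compliance
  expect_true(all(m2$limited))
  m0 <- render_monitor_trace(r$pulses[0, ], 10000, duration_ticks = 1000)
  expect_true(all(m0$voltage == 0))
  expect_error(render_monitor_trace(r$pulses, load_ohms = 0), "positive")
})
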