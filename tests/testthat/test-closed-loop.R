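# End-to-end loop fixtures: spike-triggered stimulation, the network demo
# wiring, and the three-muscle EMG / three-site stimulation demo.

loop_filtered_codes <- function(x, fs, bandpass, adc = adc_model(noise_uv_rms = 0)) {
  y <- apply_frontend_highpass(x, fs)
  y <- apply_bandpass(y, fs, bandpass[1], bandpass[2])
  quantize_samples(y, adc)
}

spike_loop_fixture <- function(seed = 1, duration_s = 1, rate_hz = 6,
                               delay_ms = 1, refractory_ms = 10,
                               window_zero_delay = FALSE) {
  fs <- 20000
  bandpass <- c(500, 5000)
  tmpl <- spike_template(fs, peak_mv = 1)
  scen <- scenario_spec(duration_s, fs, 1,
                        neurons = list(neuron_model(0, tmpl, rate_hz,
                                                    refractory_ms = 3)),
                        noise_mv_rms = 0.02,
                        artifact = list(coupling_uv_per_ua = 2,
                                        highpass_fl = bandpass[1]),
                        seed = seed)
  # tune the discriminator on the template as the front end will see it
  ft <- loop_filtered_codes(c(numeric(200), tmpl, numeric(200)), fs, bandpass)
  period <- sample_period_ticks(fs)
  spec <- if (window_zero_delay) {
    peak <- min(ft)
    window_disc_spec(peak / 2, "falling",
                     list(list(delay_ticks = 0, amplitude_min = -32768,
                               amplitude_max = 32767)),
                     dead_time_ticks = ms_to_ticks(1))
  } else template_disc(ft, period, noise_codes = 0.02 / adc_model()$lsb_mv)
  gen <- event_generator(0, "window_discriminator", source = 0L,
                         discriminator = spec)
  w <- stim_waveform(0, ms_to_ticks(delay_ms), 100, us_to_ticks(200),
                     -100, us_to_ticks(200), pins = c(0L, 1L))
  cond <- stim_condition(0, list(w),
                         list(list(gen = 0, waveform_ids = 0L, rules = list())))
  cfg <- device_config(make_channels(1), bandpass = bandpass,
                       event_generators = list(gen), conditions = list(cond),
                       seed = seed, refractory_ms = refractory_ms)
  list(cfg = cfg, scen = scen)
}

test_that("delivered stimuli equal accepted discriminator events", {
  fx <- spike_loop_fixture(seed = 2)
  res <- run_closed_loop(fx$cfg, fx$scen)
  n_events <- sum(res$records$kind == "digital_event")
  expect_gt(n_events, 2)
  expect_equal(nrow(res$pulses), n_events - nrow(res$rejected))
  expect_gt(nrow(res$pulses), 0)
  # most ground-truth spikes are detected
  det <- sum(vapply(s_to_ticks(res$truth$time_s), function(tt)
    any(abs(res$records$timestamp[res$records$kind == "digital_event"] - tt)
        <= ms_to_ticks(1.5)), TRUE))
  expect_gte(det / nrow(res$truth), 0.8)
  # stimulus events in the session match the scheduler's pulse list
  sev <- res$records[res$records$kind == "stimulus_event", ]
  expect_equal(sort(sev$timestamp), sort(res$pulses$onset))
})

test_that("closed-loop latency is bounded by a sample period plus the waveform delay", {
  fx <- spike_loop_fixture(seed = 3, window_zero_delay = TRUE)
  res <- run_closed_loop(fx$cfg, fx$scen)
  expect_gt(nrow(res$pulses), 0)
  lat <- res$pulses$onset - res$pulses$trigger_ts
  expect_true(all(lat <= sample_period_ticks(20000) + ms_to_ticks(1)))
  expect_true(all(lat >= 0))
})

test_that("the same seed produces byte-identical session files", {
  fx <- spike_loop_fixture(seed = 5, duration_s = 0.5)
  p1 <- withr::local_tempfile(fileext = ".nls")
  p2 <- withr::local_tempfile(fileext = ".nls")
  run_closed_loop(fx$cfg, fx$scen, path = p1)
  run_closed_loop(fx$cfg, fx$scen, path = p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("the network demo wiring routes four inputs to four delayed outputs", {
  # four timed inputs enter as external sources -1..-4; units 4-7 fire and
  # trigger four stimulation waveforms at distinct delays; units 0-3 mirror
  # the inputs so all 8 I/O units log network events
  conn <- rbind(
    data.frame(source = -(1:4), target = 0:3, weight_uv = 20000),
    data.frame(source = -(1:4), target = 4:7, weight_uv = 20000))
  net <- snn_network(8, snn_globals(1, 32768, 58982, 0, 0, 500), conn)
  gens_in <- lapply(0:3, function(i)
    event_generator(i, "fixed_interval", period_ticks = ms_to_ticks(50)))
  gens_out <- lapply(4:7, function(i) event_generator(i, "snn_output"))
  pins <- list(c(0L, 1L), c(2L, 3L), c(4L, 5L), c(1L, 2L))
  wfs <- lapply(1:4, function(k)
    stim_waveform(k - 1L, ms_to_ticks(k), 50, us_to_ticks(200), -50,
                  us_to_ticks(200), pins = pins[[k]]))
  cond <- stim_condition(0, wfs, lapply(1:4, function(k)
    list(gen = k + 3L, waveform_ids = k - 1L, rules = list())))
  cfg <- device_config(make_channels(1), bandpass = c(500, 5000),
                       event_generators = c(gens_in, gens_out),
                       conditions = list(cond), snn = net, seed = 7,
                       refractory_ms = 1)
  scen <- scenario_spec(0.5, 20000, 1, neurons = list(), noise_mv_rms = 0.01,
                        seed = 7)
  res <- run_closed_loop(cfg, scen)
  nev <- res$records[res$records$kind == "network_event", ]
  expect_setequal(unique(nev$source), 0:7)        # all 8 I/O units spiked
  expect_gt(nrow(res$pulses), 0)
  expect_setequal(unique(res$pulses$waveform_id), 0:3)
  # train onsets respect the configured global refractory across outputs
  onsets <- sort(unique(res$pulses$onset))
  expect_true(all(diff(onsets) >= ms_to_ticks(1)))
})

test_that("three EMG loops stimulate three sites under the global refractory", {
  fs <- 5000
  tmpl <- mup_template(fs, peak_mv = 1)
  bandpass <- c(10, 1000)
  neurons <- lapply(0:2, function(i)
    neuron_model(i, tmpl, rate_hz = 8, refractory_ms = 6,
                 coupling = as.numeric(seq_len(3) == i + 1)))
  scen <- scenario_spec(4, fs, 3, neurons = neurons, noise_mv_rms = 0.05,
                        artifact = list(coupling_uv_per_ua = 1,
                                        highpass_fl = bandpass[1]),
                        seed = 11)
  ft <- loop_filtered_codes(c(numeric(100), tmpl, numeric(100)), fs, bandpass)
  period <- sample_period_ticks(fs)
  spec <- template_disc(ft, period, noise_codes = 0.05 / adc_model()$lsb_mv)
  gens <- lapply(0:2, function(i)
    event_generator(i, "window_discriminator", source = i,
                    discriminator = spec))
  pins <- list(c(0L, 1L), c(2L, 3L), c(4L, 5L))
  wfs <- lapply(0:2, function(i)
    stim_waveform(i, ms_to_ticks(0.5), 200, us_to_ticks(200), -200,
                  us_to_ticks(200), pins = pins[[i + 1]]))
  cond <- stim_condition(0, wfs, lapply(0:2, function(i)
    list(gen = i, waveform_ids = i, rules = list())))
  cfg <- device_config(make_channels(3, rate = fs), bandpass = bandpass,
                       event_generators = gens, conditions = list(cond),
                       seed = 11, refractory_ms = 10)
  res <- run_closed_loop(cfg, scen)
  expect_gt(nrow(res$pulses), 5)
  expect_setequal(unique(res$pulses$pin_a), c(0L, 2L, 4L))  # three sites
  onsets <- sort(res$pulses$onset)
  expect_true(all(diff(onsets) >= ms_to_ticks(10)))
  expect_true(any(res$rejected$reason == "refractory"))
  # sweeps around stimuli are retrievable from the recorded session
  s <- summarize_session(res$path, sweep_source = "stim", sweep_channel = 0,
                         sweep_halfwidth_ticks = ms_to_ticks(5))
  expect_true(is.matrix(s$sweeps))
})
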