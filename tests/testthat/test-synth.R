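test_that("ground truth is exhaustive: the noiseless trace is the sum of templates", {
  fs <- 20000
  tmpl <- spike_template(fs, peak_mv = 1)
  spec <- scenario_spec(2, fs, n_channels = 2,
                        neurons = list(neuron_model(0, tmpl, 8,
                                                    coupling = c(1, 0.5))),
                        noise_mv_rms = 0, seed = 3)
  r <- synthesize_recording(spec)
  expect_gt(nrow(r$truth), 0)
  recon <- matrix(0, nrow(r$traces), 2)
  for (k in seq_len(nrow(r$truth))) {
    i0 <- r$truth$sample[k]
    idx <- i0:min(nrow(recon), i0 + length(tmpl) - 1L)
    recon[idx, 1] <- recon[idx, 1] + tmpl[seq_along(idx)]
    recon[idx, 2] <- recon[idx, 2] + 0.5 * tmpl[seq_along(idx)]
  }
  expect_equal(r$traces, recon)
})

test_that("silent neurons give pure noise and zero ground truth", {
  spec <- scenario_spec(0.5, 20000, 1,
                        neurons = list(neuron_model(0, spike_template(),
                                                    rate_hz = 0)),
                        noise_mv_rms = 0.05, seed = 1)
  r <- synthesize_recording(spec)
  expect_equal(nrow(r$truth), 0)
  expect_equal(sd(r$traces[, 1]), 0.05, tolerance = 0.05)
})

test_that("spike counts follow Poisson statistics at the configured rate", {
  counts <- vapply(1:10, function(s) {
    spec <- scenario_spec(100, 5000, 1,
                          neurons = list(neuron_model(0, spike_template(5000),
                                                      rate_hz = 10,
                                                      coupling = 0)),
                          noise_mv_rms = 0, seed = s)
    nrow(synthesize_recording(spec)$truth)
  }, 0)
  expect_true(all(abs(counts - 1000) < 3 * sqrt(1000)))
  # and the refractory period is always respected
  spec <- scenario_spec(30, 5000, 1,
                        neurons = list(neuron_model(0, spike_template(5000),
                                                    rate_hz = 50,
                                                    refractory_ms = 2,
                                                    coupling = 0)),
                        noise_mv_rms = 0, seed = 2)
  tt <- synthesize_recording(spec)$truth$time_s
  expect_true(all(diff(tt) >= 0.002))
})

test_that("same seed reproduces traces bit for bit", {
  spec <- scenario_spec(0.5, 20000, 2,
                        neurons = list(neuron_model(0, spike_template(), 20,
                                                    coupling = c(1, 0.3))),
                        noise_mv_rms = 0.02, seed = 9)
  expect_identical(synthesize_recording(spec)$traces,
                   synthesize_recording(spec)$traces)
})

test_that("sub-range artifacts are brief and saturating artifacts decay with 1/fl", {
  fs <- 20000
  traces <- matrix(0, fs, 1)                   # 1 s
  pulses <- data.frame(onset = s_to_ticks(0.2), amp1_ua = 100)
  # 100 uA x 10 uV/uA = 1 mV: within range, brief
  r <- inject_stimulus_artifact(traces, fs, pulses,
                                list(coupling_uv_per_ua = 10,
                                     highpass_fl = 500))
  changed <- which(r$traces[, 1] != 0)
  on_i <- 0.2 * fs + 1
  expect_true(all(changed >= on_i & changed < on_i + 0.002 * fs))
  # 1 mA x 10 uV/uA = 10 mV: saturating; fl = 10 Hz recovers by 0.1 s
  pulses2 <- data.frame(onset = s_to_ticks(0.2), amp1_ua = 1000)
  r2 <- inject_stimulus_artifact(traces, fs, pulses2,
                                 list(coupling_uv_per_ua = 10,
                                      highpass_fl = 10))
  i_01 <- round((0.2 + 0.1) * fs) + 1
  expect_lt(abs(r2$traces[i_01, 1]), 0.01 * 5)   # < 1% of saturation (5 mV)
  expect_gt(abs(r2$traces[on_i + 100, 1]), 0.5)  # but clearly present early
  # additivity: removing the artifact restores the input exactly
  expect_equal(r2$traces - r2$artifact_traces, traces)
  # no stimuli: identity
  r3 <- inject_stimulus_artifact(traces, fs, pulses[0, ],
                                 list(coupling_uv_per_ua = 10,
                                      highpass_fl = 10))
  expect_identical(r3$traces, traces)
})

test_that("evoked responses follow their probability, latency and refractory", {
  fs <- 20000
  tmpl <- spike_template(fs)
  nm <- neuron_model(0, tmpl, rate_hz = 0, refractory_ms = 1)
  mk <- function(p, n_stim, jitter = 0) {
    spec <- scenario_spec(n_stim * 0.02 + 1, fs, 1, neurons = list(nm),
                          noise_mv_rms = 0,
                          evoked = data.frame(unit_id = 0, probability = p,
                                              latency_ms = 2,
                                              jitter_ms = jitter))
    pulses <- data.frame(onset = s_to_ticks((seq_len(n_stim) - 1) * 0.02))
    truth0 <- synthesize_recording(spec)$truth
    evoke_responses(pulses, spec, truth0, rng_stream(5, "evoked"))
  }
  t1 <- mk(1, 50)
  expect_equal(nrow(t1), 50)                     # every stimulus evokes
  expect_equal(t1$time_s, (seq_len(50) - 1) * 0.02 + 0.002)
  expect_true(all(t1$evoked))
  expect_equal(nrow(mk(0, 50)), 0)
  n_half <- nrow(mk(0.5, 1000))
  expect_lt(abs(n_half - 500), 3 * sqrt(1000 * 0.25))
})

test_that("the EMG scenario yields three burst-modulated channels with detectable potentials", {
  emg <- synthesize_emg_scenario(duration_s = 10, seed = 4)
  expect_equal(ncol(emg$traces), 3)
  for (ch in 1:3) {
    expect_gte(nrow(emg$truth[[ch]]$bursts), 1)
    expect_gt(length(emg$truth[[ch]]$potentials), 5)
    # potentials confined to burst windows
    b <- emg$truth[[ch]]$bursts
    for (p in emg$truth[[ch]]$potentials)
      expect_true(any(p >= b$start & p <= b$end + 0.01))
  }
  # discriminator tuned to the template recovers >= 95% of ground truth
  adc <- adc_model(noise_uv_rms = 0)
  period <- sample_period_ticks(5000)
  tmpl_codes <- round(mup_template(5000, 1) / adc$lsb_mv)
  noise_codes <- 0.1 / adc$lsb_mv
  spec <- template_disc(tmpl_codes, period, noise_codes)
  hits <- 0; total <- 0
  for (ch in 1:3) {
    codes <- quantize_samples(emg$traces[, ch], adc)
    ev <- discriminate_spikes(codes, 5000, spec)
    truth_ticks <- s_to_ticks(emg$truth[[ch]]$potentials)
    total <- total + length(truth_ticks)
    for (tt in truth_ticks)
      if (any(abs(ev$timestamp - tt) <= ms_to_ticks(2))) hits <- hits + 1
  }
  expect_gte(hits / total, 0.95)
})
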