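# neuroloop

`neuroloop` is an R emulator of an autonomous, head-mounted bidirectional
brain-computer interface: a device that records multichannel extracellular
or EMG signals and delivers constant-current stimulation *contingent on the
recorded activity*, with no tether and no host computer in the loop.
Researchers use such devices to induce activity-dependent plasticity
(spike- or EMG-triggered stimulation), to bridge lost connections, and to
run artificial spiking networks between recording and stimulation sites.
The package is for experimenters and methods developers who want to design,
tune and verify closed-loop protocols — discriminator windows, gating
rules, stimulation schedules, network weights — against synthetic signals
with known ground truth before committing to hardware and animals.

## What is modelled

* **Front-end**: 0.07 Hz DC-blocking high-pass per channel, adjustable
  bandpass (0.1–2,000 Hz low cut, 100–20,000 Hz high cut), 16-bit ±5 mV
  ADC with 2.4 µV RMS noise at 5/10/20 kSps per channel, post-stimulus
  fast-settle blanking (200–3,200 µs), a ±2 g / 10-bit / 100 Sps
  accelerometer, and an 8-slot IIR filter bank with rectification and
  artifact suppression.
* **Event generators**: eight firmware generators emitting events at fixed
  or random (uniform, exponential) intervals, or acting as dual
  time-amplitude window discriminators — a threshold crossing counts as a
  spike only if the samples at one or two fixed delays after the crossing
  fall inside user-defined amplitude windows. Triggers can be gated on
  event counts in a lookback window or on analog levels.
* **Stimulator**: six output pins, one shared current source. Biphasic
  asymmetric pulses of 5 µA–10 mA and 0.01–10 ms per phase; overlapping
  waveforms interleaved with a 0.4 ms switch time (0.8 ms leading-edge
  separation); zero inter-pulse interval selects burst mode (20
  back-to-back pulses inside 2 ms); sustained rate caps of 350/s
  (full-amplitude trains at ±60 V), 700/s (±50 V) and 500/s otherwise; a
  global 10 ms refractory period across all channels; a monitor channel
  recording `V = I·R` clipped at compliance.
* **Spiking network**: up to 256 integrate-and-fire units and 2,000
  connections in signed 16-bit µV arithmetic at 10,000 updates/s. Each
  unit holds fast and slow leaky potentials (Q16 decay constants, most
  significant 16 bits kept); their difference is an alpha-like PSP, and a
  unit fires when `slow − fast > θ`, resetting to zero and enqueueing a
  spike behind the global conduction delay (≤ 3.5 ms). Units 0–7 exchange
  spikes with the event generators; units 0–15 are recorded.
* **Sessions**: chunked binary recordings interleaving int16 analog runs
  with timestamped records (digital events, condition transitions,
  stimulus events, network events), checksummed per chunk, with reader,
  summaries (event counts, envelopes, triggered sweeps) and flat-file
  export.
* **Synthetic scenarios**: Poisson spike trains with refractory periods
  rendered through parametric templates, three-muscle EMG burst scenarios,
  stimulus artifacts (brief within the ±5 mV range; saturating with
  recovery τ = 1/(2π·f_low) beyond it) and probabilistic evoked responses —
  all with exhaustive ground truth.

All timestamps are integer counts of a 10 µs master tick, so every
scheduling decision is exact and reproducible; one seed drives independent
per-component random streams.

## Worked example: spike-triggered stimulation

Synthesize one cortical channel, tune a window discriminator to the spike
template as the front end will see it, and run the loop — stimulation is
delivered 1 ms after each accepted spike, under the 10 ms global
refractory:

```r
library(neuroloop)
fs <- 20000
tmpl <- spike_template(fs, peak_mv = 1)
scen <- scenario_spec(2, fs, 1,
  neurons = list(neuron_model(0, tmpl, rate_hz = 6, refractory_ms = 3)),
  noise_mv_rms = 0.02,
  artifact = list(coupling_uv_per_ua = 2, highpass_fl = 500), seed = 2)

# discriminator tuned on the band-filtered, quantized template
ft <- quantize_samples(apply_bandpass(apply_frontend_highpass(
        c(numeric(200), tmpl, numeric(200)), fs), fs, 500, 5000),
      adc_model(noise_uv_rms = 0))
peak_i  <- which.min(ft)
thr     <- ft[peak_i] / 2
cross_i <- which(ft <= thr)[1]
disc <- window_disc_spec(thr, "falling",
  list(list(delay_ticks = (peak_i - cross_i) * sample_period_ticks(fs),
            amplitude_min = ft[peak_i] * 1.35,
            amplitude_max = ft[peak_i] * 0.65)))

gen  <- event_generator(0, "window_discriminator", source = 0L,
                        discriminator = disc)
w    <- stim_waveform(0, ms_to_ticks(1), 100, us_to_ticks(200),
                      -100, us_to_ticks(200), pins = c(0L, 1L))
cond <- stim_condition(0, list(w),
                       list(list(gen = 0, waveform_ids = 0L, rules = list())))
cfg  <- device_config(list(channel_config(0, "single_ended", fs)),
                      bandpass = c(500, 5000), event_generators = list(gen),
                      conditions = list(cond), seed = 2, refractory_ms = 10)

res <- run_closed_loop(cfg, scen)
nrow(res$truth); sum(res$records$kind == "digital_event"); nrow(res$pulses)
```

With seed 2 this prints `11`, `11`, `11`: the scenario produced 11
ground-truth spikes, the discriminator accepted all 11 (threshold −2109
codes, one window 5 ticks after the crossing), and 11 stimuli were
delivered — none dropped, since 6 Hz firing rarely collides with a 10 ms
refractory. `summarize_session(res$path)` shows the same counts recovered
from the session file (11 events on generator 0, 11 stimuli on output
pin 0), and `res$pulses$onset - res$pulses$trigger_ts` confirms the 1 ms
trigger-to-pulse delay.

A thin command-line front end is installed with the package
(`inst/cli/neuroloop`): `neuroloop validate <config.yaml>`,
`neuroloop run <config.yaml> <scenario.yaml> <out>`,
`neuroloop summarize <session>`, `neuroloop export <session> <dir>`.

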