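---
title: "Emulating an autonomous closed-loop recording and stimulation device"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Emulating an autonomous closed-loop recording and stimulation device}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroloop)
```

## What is being emulated

`neuroloop` is a software model of a head-mounted bidirectional
brain-computer interface that records multichannel extracellular or EMG
signals and delivers constant-current stimulation contingent on detected
activity, entirely autonomously. The emulator reproduces the *digital
semantics* of such a device — what is detected, when stimulation is
delivered, what is written to storage — rather than its analog electronics.
Four interacting subsystems are modelled:

1. **Analog front-end.** Each physiological channel passes a 0.07 Hz
   first-order DC-blocking high-pass, the amplifier's adjustable bandpass
   (0.1–2,000 Hz low cut, 100–20,000 Hz high cut), and a 16-bit ADC with a
   ±5 mV input range and 2.4 µV RMS input-referred noise, sampled at 5, 10
   or 20 kSps per channel. After each stimulus the amplifier can "fast
   settle", clamping outputs to baseline for 200–3,200 µs. An 8-slot IIR
   filter bank can band-filter single channels or channel pairs, rectify,
   and artifact-suppress.
2. **Event generators.** Eight firmware objects emit timestamped events on
   fixed, uniform-random or exponential-random schedules, or act as dual
   time-amplitude window discriminators: a threshold crossing is accepted
   as a spike only if the samples at one or two configured delays after the
   crossing fall inside closed amplitude windows. Candidate triggers can be
   gated on event counts in a lookback window or on analog levels.
3. **Stimulator.** Six output pins driven by a single shared current
   source deliver biphasic, possibly asymmetric, constant-current pulses
   (5 µA–10 mA, 0.01–10 ms per phase) within a ±60 V compliance range.
   Overlapping requests are interleaved with a 0.4 ms switching time
   between different pin pairs; an inter-pulse interval of zero selects
   back-to-back burst mode (up to 20 pulses in 2 ms). Sustained rates are
   capped at 350/s for full-amplitude trains at ±60 V, 700/s at ±50 V and
   500/s for normal amplitudes, and a global refractory period (default
   10 ms) keeps pulse-train onsets apart across *all* channels so that
   stimulus-evoked activity cannot re-trigger stimulation.
4. **Spiking network.** An integrate-and-fire network of up to 256 units
   and 2,000 connections runs at 10,000 updates per second in signed 16-bit
   arithmetic. Each unit keeps a fast and a slow leaky potential; their
   difference forms an alpha-like post-synaptic potential, and a unit fires
   when slow − fast strictly exceeds the threshold, resetting both
   potentials and enqueueing a spike that reaches targets after the global
   conduction delay (at most 3.5 ms). The first eight units exchange spikes
   with the event generators; spikes of the first sixteen are recorded.

A synthetic scenario generator closes the loop: it produces ground-truth
spike trains rendered through parametric templates, EMG bursts of
motor-unit potentials, Gaussian noise, stimulus artifacts, and
probabilistic stimulus-evoked spikes, so every subsystem can be verified
end-to-end without hardware.

## The master timebase

All timestamps are integer counts of a 10 µs master tick from session
start. This tick was chosen because it divides every module clock: the ADC
sample periods (50/100/200 µs), the 0.1 ms network update step, and the
0.01 ms minimum stimulus phase width. Integer ticks make every scheduling
decision exactly reproducible and testable; no wall-clock time appears
anywhere. Timestamps are held in doubles (a 24 h session exceeds the 32-bit
integer range; doubles carry integers exactly to 2^53).

## Fixed-point arithmetic choices

The network engine is meant to be *bit-faithful*, so its rounding rules are
pinned explicitly:

* **Decay.** "Multiply by a Q16 decay constant keeping the most significant
  16 bits" is implemented as `floor(p * d / 2^16)` — an arithmetic right
  shift, flooring toward −∞ for negative potentials. Truncation toward zero
  is the plausible alternative; floor was chosen because it is what a
  hardware shift of the 32-bit product register produces, and the test
  suite pins it against an independent long-division oracle over 10^5
  random operand pairs.
* **Saturation.** Weight and bias deliveries saturate at the int16 bounds
  rather than wrapping; wraparound would create spurious spikes from large
  excitatory volleys. Deliveries within one step are summed in wide
  precision and clamped once per sub-step.
* **Bias spikes** add the bias strength to *both* potentials, exactly like
  a normal incoming connection; the hardware description does not say which
  potential receives bias, and treating it as an ordinary weight keeps the
  PSP shape of bias input identical to synaptic input.
* **PRNG.** The hardware bias generator is unpublished. The emulator uses a
  32-bit linear congruential stream (constants 1664525 / 1013904223), with
  the top 16 bits of the state compared against the Q16 bias chance — a
  documented, exactly reproducible choice. The stream is only consumed when
  the bias chance is nonzero.
* **Threshold** comparison is strict (`>`), reading "exceeding threshold".
* **External spikes** from the event generators are delivered on the next
  network step boundary after their event tick (an effective input delay of
  one step), while internal spikes traverse the configured conduction
  delay.

The 10,000-step bit-exactness suite compares the vectorized engine
state-for-state against a deliberately naive scalar reference
implementation, so an error in either rounding rule or the update order
would surface immediately.

## Scheduler semantics

The shared current source imposes a total order on pulses. The emulator's
policy, where the hardware description leaves freedom:

* Interleaving is first-come-first-served by requested onset, ties broken
  by ascending waveform id. A pulse on a different pin pair starts no
  earlier than the previous pulse's end plus the 0.4 ms switching time
  (hence the 0.8 ms leading-edge separation of two simultaneously
  triggered 0.4 ms waveforms); same-pin pulses may follow immediately,
  which is what makes zero-IPI burst trains gapless.
* The global refractory window is half-open, `[onset, onset + 10 ms)`: a
  trigger arriving exactly 10 ms after the previous train onset is
  accepted. It applies to pulse-train onsets — all waveforms scheduled from
  one accepted trigger count as one train.
* Rate caps drop excess triggers rather than delaying them; delaying would
  silently distort closed-loop latency. Drops are logged with reasons
  (`refractory`, `rate_cap`, or the failing gate rule) and never raised as
  errors. The compliance-dependent caps (350/s at ±60 V, 700/s at ±50 V)
  apply to trains at or above 1 mA; everything else is capped at 500/s over
  a sliding one-second window. Burst-mode pulses are exempt within one
  train; the train then counts with its full pulse count in the window.
* Condition sequencing is time-based in this release: each condition runs
  for its configured duration, the last one to the end of the session.
  (Count-based progression can be composed by the caller from the gating
  rules; the hardware leaves the progression mechanism unspecified.)

## Discriminator semantics

A window tests the *single sample* at the configured delay after the
crossing, not any sample in a span — the classic time-amplitude box of
sweep-based discriminator setups. Whether real firmware tests one sample or
a span is not documented; the single-sample choice is flagged here because
it is the stricter interpretation and users tuning windows should place
them on the template sample grid. Threshold crossings are detected as a
sign change of `sample − threshold` between consecutive samples, with no
sub-sample interpolation, and the default dead time is 1 ms. In the
closed-loop runner the *decision* for a spike is available only once its
last window has been tested, so trigger-to-pulse latency is bounded by the
last window delay plus one sample period plus the waveform's configured
delay; with a zero-delay window this reduces to one sample period.

## The synthetic scenarios

The generator emulates the statistical structure the device cares about,
not biophysics:

* Spike trains are Poisson with an absolute refractory period; the
  exponential gap rate is adjusted so the configured mean rate is preserved
  despite the dead time. The default extracellular template is a biphasic
  0.6 ms waveform (sharp negative peak, smaller positive overshoot), and
  the EMG motor-unit potential a slower 4 ms biphasic shape — both
  parametric and user-overridable, since real shapes vary.
* Stimulus artifacts follow the two regimes seen in practice: a coupled
  amplitude within the ±5 mV input range produces a brief biphasic
  transient confined to under 2 ms; beyond the range the amplifier
  saturates and the trace shows a step at the rail decaying exponentially
  with τ = 1/(2π·f_low), so recovery scales with the inverse of the
  high-pass setting (≈ 0.1 s at 10 Hz). The proportionality is the modelled
  fact; the specific first-order form is this package's choice. Artifact
  coupling amplitudes (µV per µA) are order-of-magnitude defaults exposed
  in the scenario, as no quantitative couplings are published.
* Evoked responses insert a spike after each stimulus with configured
  probability, latency and Gaussian jitter, respecting the unit's
  refractory period; the 1–10 ms fast-excitation window seen cortically is
  the intended regime. Post-stimulus inhibition can be emulated by lowering
  baseline rate; it is not modelled explicitly.
* The three-muscle EMG scenario staggers 0.35 s bursts (≈0.8/s per channel,
  60/s potentials inside a burst, ≥5 ms separation so potentials remain
  individually discriminable) across three channels, emulating three
  independent EMG-triggered stimulation loops.

Because every trace deviation from noise is attributable to a listed
ground-truth event, passing tests show the *device logic* is right. They do
not show robustness to real-data phenomena the generator omits: overlapping
spike waveforms, electrode drift, non-Gaussian noise, movement artifacts,
or unit instability.

## Session format

Sessions are chunked binary files: a serialized header (configuration
snapshot, channel map, tick size), then analog chunks (int16 code runs with
channel, start tick and period) merged in time order with record chunks
(timestamp, class, source, payload for digital events, condition
transitions, stimulus events and network events). Each chunk carries an
Adler-32 checksum, chosen over CRC-32 because it computes exactly with
vectorized arithmetic in R; the integrity guarantee (detecting truncation
and corruption, with the failing offset reported) is what matters, not the
checksum family. The on-card layout of the real device is unpublished —
this format targets the same information content, not byte compatibility.
Timestamps are stored per block, not per sample.

## Problem sizes in the test suite

The suites run end-to-end loops of 0.5–4 s at 5–20 kSps, 10,000-step
network runs on 12–20-unit nets against the scalar reference, 10^5
random fixed-point operand pairs, and 10 s EMG scenarios (≈300 ground-truth
potentials), which exercise every code path while keeping a full run in the
low minutes on one CPU. All statistical assertions use 3σ bands at these
sizes.

## Known limitations

* Power, battery, infrared link, impedance testing and the analog circuit
  interior are out of scope by design.
* The closed-loop runner assumes one common sample rate across enabled
  channels and ADC-channel discriminator sources; per-channel rates and
  filter-bank sources are available through the offline functions.
* Filter corner frequencies are honored, but amplifier transfer functions
  beyond first-order/Butterworth corners are not modelled.
* In-vivo findings obtained with such devices (plasticity, evoked-response
  magnitudes, sleep structure) are outside what a desk-scale emulator can
  or should reproduce; only the device semantics are claimed.
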