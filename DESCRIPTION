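Package: neuroloop
Title: Emulator for an Autonomous Closed-Loop Neural Recording and
    Stimulation Device
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Software emulation of a head-mounted bidirectional
    brain-computer interface that performs activity-dependent stimulation
    autonomously: a multichannel analog front-end model (bandpass
    filtering, 16-bit ADC quantization, fast-settle blanking, an 8-slot
    IIR filter bank), firmware event generators with dual time-amplitude
    window spike discrimination and trigger gating, a 6-channel
    constant-current stimulator with pulse interleaving, burst mode,
    rate caps and a global refractory period, and a bit-faithful
    fixed-point integrate-and-fire spiking neural network. A synthetic
    scenario generator produces extracellular and EMG signals with
    ground truth, stimulus artifacts and evoked responses so the whole
    loop can be exercised and verified without hardware. Sessions are
    recorded in a chunked binary format interleaving analog samples with
    timestamped event records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
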