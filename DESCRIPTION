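Package: amcoder
Title: Amplitude-Modulation Coding Analysis for Auditory Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how auditory neurons and behaving animals encode
    sinusoidal amplitude modulation (AM). Synthesizes SAM-noise, dynamic random
    chord (DRC) and pure-tone stimuli; simulates phase-locked spike trains,
    linear-nonlinear-Poisson responses and lick-response sessions; quantifies
    temporal and rate coding with phase-projected vector strength and ROC-based
    sensitivity (d-prime) with interpolated modulation-depth thresholds;
    estimates spectrotemporal receptive fields with evidence-optimized
    smoothness priors (ASD) and a multilinear context-gain-field model fitted by
    alternating least squares under multiple input-intensity scalings, scored by
    cross-validated normalized predictive power; and simulates behavioral
    response latencies with a population threshold-crossing decoder.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
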