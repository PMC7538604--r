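Package: bulbsim
Title: Olfactory Bulb Circuit Simulation with One-Shot Spike-Timing Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the signal transformations of the mammalian main
    olfactory bulb as a layered pipeline: synthetic odor scenes in receptor
    space, olfactory sensory neuron populations with heterogeneous EC50s
    extending dynamic range beyond the single-receptor Hill limit, glomerular
    relational normalization and non-topographical contrast enhancement, and a
    gamma-discretized spiking attractor network in the external plexiform
    layer whose granule-cell inhibition is learned one-shot by local
    spike-timing rules. Trained networks identify known odors online, without
    catastrophic forgetting, under heavy Bernoulli sensor occlusion and
    multiplicative plume noise. Includes evaluation harnesses (occlusion
    sweeps, forgetting curves, nearest-neighbor baselines), CSV/YAML/JSON
    interchange, and model serialization.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
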