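Package: spilinc
Title: Unsupervised Liquid-State-Machine Computing with Spike-Timing-Dependent Plasticity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Clock-driven simulator for single-liquid spiking neural networks
    (Liquid-SNN) and liquid ensembles (SpiLinC) that learn without labels.
    Leaky integrate-and-fire neurons with adaptive thresholds form a sparse
    random recurrent liquid; power-law weight-dependent STDP adapts the
    input synapses; excitatory neurons are tagged post hoc with the classes
    that drove them, and test patterns are classified from per-class average
    spike counts, optionally pooled over an ensemble of liquids trained on
    overlapping input partitions. Includes Poisson rate encoding of images
    and channel-by-time intensity envelopes, synapse-count and ensemble
    sizing arithmetic, synthetic dataset generators for both modalities, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
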