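Package: latwta
Title: Spike-Latency Coding and Temporal Winner-Take-All Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing how much stimulus information is carried by
    the latencies of the first few spikes of sensory neurons.  Implements
    nth-spike latency distributions and level-curve tuning with cosine fits,
    coincidence-detector and leaky-integrator stimulus-onset detection with
    ROC characterisation, the n-spike temporal winner-take-all (race to
    threshold) readout for single cells, populations and multi-alternative
    tasks, trial-shuffle correlation analyses, and a seeded inhomogeneous
    Poisson spike-train generator that emulates trial-aligned population
    recordings from primary visual cortex.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
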