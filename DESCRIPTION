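Package: boutscape
Title: Bistable Attractor Modeling and Microstructure Analytics for Feeding Bouts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how feeding-bout fragmentation arises from
    bistable neural population dynamics. Provides a stochastic Wilson-Cowan
    excitatory/inhibitory simulator driven by a lognormal renewal process of
    interruption pulses and tonic current injections, a quasi-static
    one-dimensional reduction with potential-landscape and barrier analysis,
    behavioral bout segmentation and microstructure statistics (interruptions,
    terminations, permutation Kolmogorov-Smirnov tests, Bernoulli GLMs),
    fiber-photometry style event-aligned quantification (z-scoring, peri-event
    averages, AUC, variance partitioning), and a seeded synthetic-session
    generator so the full pipeline is testable end to end.
License: MIT
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
    jsonlite
Config/testthat/edition: 3
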