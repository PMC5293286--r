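Package: effspike
Title: Efficient Predictive-Coding Spiking Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates networks of leaky integrate-and-fire neurons derived
    from greedy minimization of a signal-coding error plus linear and
    quadratic spike costs, with synaptic transmission delays, membrane
    noise and spike failure. Provides generators for smoothed-white-noise
    and circular Gaussian-bump inputs, spike-train statistics (multi-unit
    activity, shuffle-corrected spike-triggered MUA, Up-state detection,
    inter-burst-interval and duration statistics, CV2, synchrony), and an
    efficiency analysis that sweeps the cost plane to locate the optimal
    working regime where coding error and spike cost are jointly minimal.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    MASS,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
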