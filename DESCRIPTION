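Package: cnapsim
Title: Filter-Based Simulation of Compound Nerve Action Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Efficient simulation of electrically evoked compound nerve action
    potentials (CNAPs) recorded from peripheral nerve. Single fiber action
    potentials are reconstructed from per-compartment transmembrane current
    templates by convolution with zero-inserted shift filters that encode the
    recording sensitivity function (lead field) of the electrode, in the time
    or frequency domain, and are validated against brute-force weighted
    summation. Includes linear interpolation of action potential templates
    across fiber diameters on geometric diameter grids, monopolar and dipolar
    source representations, analytic and tabulated recording sensitivity
    functions, fiber population construction from diameter histograms
    (inverse-transform or bin-center sampling), conduction velocity models,
    myelinated fiber ultrastructure geometry, and CNAP summary metrics
    (peak-to-peak amplitude, negative-peak latency, discrepancy statistics,
    amplitude-distance power fits).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
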