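Package: motifavoid
Title: Motif-Avoidant Attractors in Asynchronous Boolean Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and analysis of motif-avoidant attractors (MAAs) in
    asynchronous Boolean networks. Provides a .bnet parser and writer, signed
    interaction-graph inference, explicit state-transition graphs, attractor
    and minimal-trap-space computation, structural exclusion criteria
    (cycle signs and linear cuts), node-deletion reduction, linear (delay)
    extensions with projected state-transition graphs and delay-count bounds,
    canalization measures (sensitivity and effective connectivity), and
    critical N-K random Boolean network ensemble experiments with Wilson
    confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
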