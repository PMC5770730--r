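Package: monoadapt
Title: Neuroadaptation Modeling of Chronic Antidepressant Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a six-unit recurrent firing-rate network of the three
    monoaminergic brain nuclei (dorsal raphe, locus coeruleus, ventral
    tegmental area) and three associated non-monoaminergic transmitter
    systems (CRF, galanin, glutamate), together with the homeostatic
    receptor-strength adjustment process by which the network adapts to
    chronically maintained antidepressant drugs. Provides drug regimens
    acting on transporters and receptors, genetic-algorithm calibration of
    model parameters against acute-response targets, stochastic
    error-reducing adaptation pathways with terminal-adaptation
    certification, and exhaustive breadth-first elaboration of the receptor
    adjustment tree with adapted-state and therapeutic-monoamine
    classification for in-silico estimation of heterogeneous antidepressant
    efficacy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
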