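Package: assemblyreader
Title: Cell-Assembly Detection and Downstream Reader Analysis for Spike Trains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects candidate cell assemblies in multi-unit spike trains
    (PCA with a Marcenko-Pastur eigenvalue threshold, fixed-point ICA, Otsu
    membership), computes member-only assembly activation strength and
    activation events, quantifies downstream "reader" responses with
    Monte-Carlo peri-event time histogram bands, tests whether reader
    responses are collective (supralinearity against a linear readout,
    identity selectivity), measures pattern completion (sigmoid subset
    responses) and pattern separation (Hoyer sparsity, discrimination
    index), detects pre/post changes in assembly-reader coupling, and
    provides a hierarchical bootstrap for nested designs. A synthetic
    two-structure spike-train generator with a planted ground-truth
    manifest makes every stage testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
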