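Package: cogrehab
Title: Adaptive Cognitive Rehabilitation Profiling and Training Engine
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds multidimensional cognitive profiles from heterogeneous
    neuropsychological test batteries by weighted score aggregation,
    contextualizes them against demographically stratified normative data,
    selects and parameterizes cognitive training tasks by a coverage-distance
    ranking, adapts task difficulty in-session with a threshold controller
    that keeps performance in a target band, and updates the profile between
    sessions by a minimal-change (belief-revision) operator over a
    finite-domain constraint language. A synthetic-patient simulator lets the
    full closed loop of profiling, selection, adaptation and revision be
    exercised end to end without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
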