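Package: entolat
Title: Lateralized Visual Responses in Single-Unit Spike Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for trial-aligned single-unit spike recordings
    under lateralized visual stimulation (contralateral, ipsilateral and
    bilateral flashes). Builds peristimulus time histograms, extracts
    spontaneous rates and ON/OFF peak rates and latencies, screens units for
    visual responsiveness, separates bilaterally from contralaterally
    responsive units by a three-criterion rule (ipsilateral 4-sigma peak,
    rank-sum tests on peaks and on window firing rates), types
    excitatory/suppressive binocular integration, and runs rank-based
    factorial statistics (Scheirer-Ray-Hare test with Kruskal-Wallis
    eta-squared effect sizes, Dunn post-hoc comparisons, Wilcoxon rank-sum
    with continuity correction, and a pooled two-proportion z test). Includes
    an inhomogeneous-Poisson spike-train simulator with ground-truth unit
    archetypes for parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
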