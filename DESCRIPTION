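Package: riverwq
Title: River Water Quality Indices and Lockdown-Phase Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes four formula-defined river water quality indices --
    a weighted-arithmetic Modified Water Quality Index (MWQI), the
    Heavy-metal Pollution Index (HPI/HMI), the Hakanson potential
    ecological risk index (RI) and the Carlson Trophic State Index (TSI)
    -- together with their qualitative classification schemes, from
    per-site physico-chemical and biological measurements. Includes
    phase-comparison statistics (descriptive summaries, percent change,
    Pearson correlation matrices with significance stars, one-way ANOVA
    with Fisher's LSD post-hoc), a seed-deterministic truncated-normal
    synthetic sampler emulating an 11-site, three-phase monitoring
    design, and CSV/YAML readers and writers for samples, standards and
    results.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tibble,
    readr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
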