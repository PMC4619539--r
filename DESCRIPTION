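Package: mcramp
Title: Minimal Common Region Amplification Hotspots and qPCR Copy-Number Calling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects recurrent minimal common regions (MCRs) of genomic
    amplification from segmented array-CGH copy-number profiles using a
    sweep-line support profile (hotspots require support from at least three
    samples and span at most 2.5 Mb), quantifies locus copy number from
    genomic qPCR cycle-threshold data by efficiency-corrected relative
    quantification (E^dCt / Pfaffl, with ddCt as the E = 2 special case) over
    a reference gene and diploid calibrator, classifies fold changes into
    five copy states, and relates copy state to tumor thickness
    (Mann-Whitney), cross-platform concordance (sign consistency, Pearson)
    and metastasis-free / overall survival (Kaplan-Meier, log-rank,
    Mantel-Haenszel hazard ratio). Includes a synthetic-cohort generator with
    planted amplicons, copy-state-dependent thickness, a generative Ct-level
    qPCR model and exponential event times, so the full pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    tools,
    survival,
    yaml,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
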