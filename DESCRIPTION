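Package: itraqnet
Title: Differential Proteomics, Interaction-Network and qPCR Analysis for
    Chronic Low-Dose Radiation Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for isobaric-tag (iTRAQ 4-plex) differential
    proteomics in population studies of chronic low-dose ionizing radiation.
    Calls differentially regulated proteins from reporter-ion ratios using a
    duplicate-with-imputed-third-replicate Student's t-test and
    Benjamini-Hochberg correction, performs Fisher's exact over-representation
    against user-supplied annotation sets, builds fold-change-annotated
    protein-protein interaction networks with giant-connected-component
    permutation significance and multiplicative hub scoring, quantifies qPCR
    validation data with the dual-reference 2^-ddCt method, and stratifies
    subjects into dose groups from survey-meter dosimetry. A synthetic-data
    module generates every pipeline input with planted ground truth so the
    whole analysis is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
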