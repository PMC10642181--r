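Package: crctriage
Title: Germline Variant Triage for a Hereditary Colorectal Cancer Gene Panel
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for triaging germline variants from a 14-gene hereditary
    colorectal cancer sequencing panel. Implements the multi-stage filter
    funnel used to prioritise pathogenic/likely pathogenic germline variants
    (PASS status, functional class and location, population allele frequency,
    ClinVar category, recurrent-indel artifact detection, depth of coverage,
    deduplication), a parallel funnel for variants of uncertain significance,
    classification by the ACMG/AMP combining rules with a conservative
    auto-assigner for computable evidence codes, pseudogene-aware verification
    via a confirmed/failed ledger (PMS2/PMS2CL homology), and cohort summary
    statistics (carrier yields, per-gene distributions, novelty, IHC
    concordance, contingency-table tests). A synthetic-cohort generator with
    per-variant truth tables makes every pipeline stage testable offline, and
    a deterministic scenario reproduces the published cohort surfaces from
    transcribed tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
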