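#!/usr/bin/env Rscript
# Classification and verification: ACMG tiers over the prioritized variants
# (curated printed tiers over the computable auto-evidence), then the
# pseudogene-aware verification ledger and patient resolution.

suppressPackageStartupMessages(library(crctriage))
dir.create("results", showWarnings = FALSE)

sc <- paper_scenario()
cfg <- filter_config()
funnel <- run_pgv_funnel(sc$records, cfg, n_samples = nrow(sc$registry))

classified <- classify_cohort(funnel$unique_variants,
                              records = funnel$records, curated = sc$curated)
write_tsv(classified, "results/03_classification.tsv")
pgvs <- pgv_set(classified)
message(sprintf("%d unique pathogenic/likely pathogenic variants", nrow(pgvs)))

calls <- expand_carriers(funnel$unique_variants, tiers = classified)
verified <- apply_ledger(calls, sc$ledger)
message(sprintf("verification: %d calls in, %d verified, %d confirmed absent, %d unverified (pseudogene homology)",
                nrow(calls), nrow(verified$verified), nrow(verified$removed),
                nrow(verified$unverified)))

resolution <- resolve_patients(sc$registry$patient_id, verified)
write_tsv(resolution, "results/03_patient_resolution.tsv")
message(sprintf("resolved patients: %d of %d",
                sum(resolution$status == "resolved"), nrow(resolution)))
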