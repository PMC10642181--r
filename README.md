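# crctriage

Germline variant triage for a 14-gene hereditary colorectal cancer (CRC)
sequencing panel.

Multigene panel screening of CRC patients produces 100–200 annotated variant
calls per individual, of which at most a handful are clinically actionable.
`crctriage` implements, as tested and reusable R code, the triage analysis
used to find pathogenic and likely pathogenic germline variants (PGVs) in a
107-patient early-onset CRC cohort screened with a 14-gene panel (*APC*,
*BMPR1A*, *EPCAM*, *MLH1*, *MSH2*, *MSH6*, *MUTYH*, *PMS2*, *POLD1*, *POLE*,
*PTEN*, *SMAD4*, *STK11*, *TP53*). It is aimed at analysts who need the
whole chain — filtering, classification, verification, cohort statistics —
to be explicit, configurable and testable offline.

## What it computes

**Filter funnel.** Ordered, individually reportable stages over the merged
per-sample annotation table:

1. caller `PASS` status;
2. function/location: synonymous calls removed (unless ClinVar-pathogenic or
   at an annotated exon boundary — the "synonymous rescue" that recovers
   splice-disrupting calls such as *MLH1* c.1731G>A), locations restricted
   to exonic/flanking (intronic offset ≤ 20 bp by default);
3. population frequency: retain MAF < 0.05 or unknown;
4. ClinVar category: benign/likely-benign removed;
5. recurrent-indel artifact flag: an indel key carried by > 20 % of samples
   is an alignment artifact (a deterministic replacement for manual
   genome-browser review);
6. depth of coverage: retain > 30×;
7. deduplication to unique variants (identity = gene + normalized cDNA HGVS).

A parallel funnel extracts the variant-of-uncertain-significance (VUS)
surface from ClinVar "uncertain significance" calls.

**ACMG/AMP classification.** The 28 evidence codes (PVS1, PS1–4, PM1–6,
PP1–5, BA1, BS1–4, BP1–7) with native or overridden strengths are combined
into the 5-tier verdict (P / LP / VUS / LB / B) by the standard combining
rules, e.g. Pathogenic ⇐ PVS1 ∧ (≥1 PS ∨ ≥2 PM ∨ PM+PP ∨ ≥2 PP), and
contradictory evidence resolves to VUS. A conservative auto-assigner covers
the criteria computable from the record alone (PVS1, PM2, PM4, BA1, BS1,
BP4/PP3, BP7); curated evidence — including the published per-variant tiers
— merges over it.

**Pseudogene-aware verification.** Calls whose coding span intersects a
homology region (default: *PMS2* c.1145–2589, the 3' segment shared with the
pseudogene *PMS2CL*) are never counted as verified findings without a
`confirmed_present` entry in the verification ledger; `confirmed_absent`
entries remove calls and may leave patients "unresolved".

**Cohort statistics.** Carrier yields, per-gene distributions, novelty
counts, IHC concordance, and contingency-table tests (two-sided Fisher under
the minimum-likelihood convention, Yates-corrected χ², Wilcoxon rank-sum).

A synthetic-cohort generator plants PGVs, VUSs, pseudogene shadows and
artifacts over a designed-to-fail background so that every funnel stage's
behaviour is exactly checkable against a truth table.

## Worked example

```r
library(crctriage)

sc  <- paper_scenario()   # deterministic reconstruction of the cohort
run <- run_triage(sc$records, sc$registry, sc$curated, sc$ledger,
                  aggregates = load_fixture("table2_aggregates"))
run$summary
#> <cohort_summary> 107 patients
#>   PGV carriers: 27 (25.23%) pre-verification; 25 (23.36%) verified
#>   unique PGVs: 24; MMR (Lynch) carriers: 14 (13.08%)
#>   novel unique PGVs: 10 (5 in MMR genes)
#>   unique VUSs: 21 (10 in MMR genes), 35 carriers (9 also carry a PGV)
```

Reading: 27 of 107 patients carried a prioritised P/LP variant before
orthogonal verification; long-range PCR showed the *PMS2*
c.2192_2196delTAACT call to be pseudogene-derived in all three carriers,
dropping the verified yield to 25 patients (23.4 %) and leaving the two
patients with no other finding unresolved. Fourteen patients carry a
verified mismatch-repair variant (Lynch syndrome, 13.08 %). The funnel
stages and association tests are inspectable:

```r
run$funnel$stages          # per-stage retained record / unique counts
run$summary$association    # Fisher p = 0.156 (age), Yates chi-sq p = 0.697 (gender)
```

The numbered scripts under `analysis/` run the same pipeline as a narrative
workflow (`01_simulate.R` synthetic validation, `02_triage.R` funnels,
`03_classify_verify.R` classification + ledger, `04_cohort_stats.R`
summary), writing their tables under `results/`.

## Scope

The package starts from annotated per-sample variant tables; read alignment,
variant calling, wet-lab verification chemistry and external annotation
services are out of scope. Raw-cohort totals that depend on the upstream
caller (e.g. the 15,063-call pre-filter load) are not reproduced here, as
they require the original sequencing reads.
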