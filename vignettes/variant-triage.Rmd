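---
title: "Triage of germline variants from a hereditary CRC gene panel"
author: "crctriage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triage of germline variants from a hereditary CRC gene panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crctriage)
```

## The problem

Panel sequencing of patients with suspected hereditary colorectal cancer
yields on the order of 100–200 annotated variant calls per individual across
the 14 screened genes. Almost all of these are common polymorphisms,
caller noise or benign variation; the clinically meaningful output is a
short list of pathogenic/likely pathogenic germline variants (PGVs) per
patient, a verified carrier yield for the cohort, and an accounting of the
variants of uncertain significance (VUSs). Two features make this more than
a filtering exercise: a synonymous annotation can hide a splice-disrupting
allele, and the 3' exons of *PMS2* are (near-)identical to the pseudogene
*PMS2CL*, so a short-read call there cannot be attributed to the functional
gene without gene-specific verification.

`crctriage` implements that whole chain as explicit, configurable stages.
This vignette is the package's account of the method: the model behind each
stage, the tunable parameters and their defaults, what the synthetic-data
generator does and does not emulate, and the design choices made where the
procedure was genuinely open.

## The filter funnel

The PGV funnel applies, in order: caller `PASS` status; functional class and
location; population allele frequency; ClinVar category; a recurrent-indel
artifact flag; depth of coverage; and deduplication. Each stage records the
retained record count and retained unique-variant count, so the funnel is a
monotone sequence by construction (asserted at run time). The final identity
of a variant is its `gene + normalized cDNA HGVS` key — transcript versions
are deliberately ignored, since annotation releases drift while the coding
change names the same allele.

Parameters, with units and defaults:

| parameter | default | meaning |
|---|---|---|
| `maf_max` | 0.05 | retain population MAF strictly below this; a missing MAF is retained as "rare, unknown" |
| `depth_min` | 30 reads | retain depth strictly greater (30× or less is excluded) |
| `flank_bp` | 20 bases | intronic offset still counted as "flanking"; the canonical ±1/±2 dinucleotide always is |
| `artifact_sample_fraction` | 0.2 | indel keys carried by more than this fraction of samples are artifacts |
| `synonymous_rescue` | on | keep synonymous calls that are ClinVar pathogenic-tier or splice candidates |

Three of these encode readings of an underspecified protocol, chosen once:

* **Depth.** One description of the cut-off reads "30× or less excluded",
  another "less than 30×". The stricter reading (retain depth > 30) is used
  for both funnels; the threshold is configurable.
* **Flanking width.** "Flanking regions" is not quantified upstream; 20
  intronic bases is a conventional panel-report window and is configuration,
  not biology.
* **Artifacts.** Manual genome-browser inspection found recurrent
  insertion/deletion artifacts "in multiple samples"; the package replaces
  this with a deterministic rule (indel key in > 20 % of samples), applied
  cohort-wide before the depth stage. Substitutions are never flagged.

The synonymous rescue deserves emphasis: a synonymous-annotated variant at
the last base of an exon can destroy the splice donor/acceptor. Exonic
positions within `flank_bp = 2` coding bases of an annotated exon boundary
are flagged splice candidates. The default panel ships a deliberately
partial boundary list (only junctions adjacent to variants the packaged
fixtures classify as splice-affecting): no public exon table is bundled, so
boundaries are configuration supplied with the panel definition. The
ClinVar-pathogenic arm of the rescue is independent of boundaries and is
what recovers the known synonymous-but-pathogenic *MLH1* allele even with an
empty boundary list.

The VUS funnel runs the same cut-offs in the narrative order used for
uncertain-significance accounting: ClinVar "uncertain" selection, depth,
exonic non-synonymous restriction, frequency, deduplication. The two
funnels' filters commute at the record level; the stage order only affects
intermediate counts, which is why each funnel fixes the order its published
counts were reported in.

## ACMG/AMP classification

Evidence codes are combined at their *effective* strengths (native strength
by prefix, overridable per code, e.g. `PS4:moderate`). The combining table
is implemented clause by clause; conflicting evidence — any pathogenic-side
rule and any benign-side rule firing together — resolves to VUS, the
guidelines' stated convention. Two deliberate readings:

* **PVS1 alone is a VUS.** The strict combining table has no
  likely-pathogenic clause for a lone very-strong criterion, although some
  annotation tools emit LP for it.
* **Totality.** The implementation is verified against an independently
  coded rule-table oracle over the full reduced criterion lattice
  (PVS1 ∈ {0,1}, PS ∈ 0–3, PM ∈ 0–5, PP ∈ 0–5, BA1 ∈ {0,1}, BS ∈ 0–3,
  BP ∈ 0–3), together with monotonicity: without benign evidence, adding
  pathogenic evidence never lowers the tier.

The auto-assigner is deliberately conservative: it assigns only criteria
computable from the annotation record itself — PVS1 (null variant in a gene
with a loss-of-function disease mechanism; *POLD1*/*POLE* are excluded
because their mechanism is proofreading-domain missense), PM2 (MAF missing
or < 1e-4), PM4 (in-frame indel), BA1 (MAF > 0.05), BS1 (MAF > 1e-3 without
BA1), PP3/BP4 (≥ 3 of 4 concordant prediction calls), BP7 (benign-predicted
synonymous without splice candidacy). The frequency thresholds for PM2/BS1
are package decisions, not published facts. Everything requiring database
lookups or segregation data enters through curated evidence, which wins per
code; a curated final tier wins outright. The published per-variant tiers
are therefore carried as curated evidence in the packaged fixtures — the
full manual assignments behind them are not recomputable offline.

## Verification and the pseudogene problem

The verification ledger records, per (variant, sample), orthogonal
confirmation: `confirmed_present`, `confirmed_absent`, or `unverified`.
Applying it never adds calls and is idempotent. A call whose coding span
intersects a homology region is withheld from verified yields unless
explicitly `confirmed_present` — an unverified call in a pseudogene-shadowed
region is never a verified finding (the conservative default mirrors how
such patients are reported "unresolved").

The shipped homology region is *PMS2* c.1145–2589 — the 3' coding segment
(exons 11–15 of NM_000535.7) shared with *PMS2CL*. Only the existence of a
3' homologous segment is established upstream; the exact boundary is a
configuration default chosen so that both observed 3'-end *PMS2* variants
(c.1579_1580delAG, verified present by long-range PCR, and
c.2192_2196delTAACT, shown absent) fall inside it.

## The synthetic-cohort generator

`generate_cohort()` exists so every stage is testable without any external
data. It is truth-table-driven rather than a free simulation: every
background record is *constructed to fail exactly one chosen stage*
(non-PASS status; synonymous; deep-intronic location; common allele,
MAF ~ U(0.05, 0.5) with a benign ClinVar entry; rare benign-annotated; low
depth) or to survive as rare unclassifiable noise, so funnel-stage counts
are exactly checkable, not just statistically. Planted PGVs/VUSs, pseudogene
shadows (annotated identically to real calls) and recurrent-indel artifacts
are laid over that background. Defaults encode the study's conditions:
100 patients, 100–200 calls per individual, negative-binomial depth around
604×, registry ages from a discretised truncated normal (mean 36, sd 9,
bounds 18–58, median ≈ 37 — a stand-in for the reported mean 35.6 (SD 8.7);
no distribution family is published), balanced gender, colon:rectum ≈ 3:1.
All randomness flows from the single config seed.

What the generator does *not* emulate: linkage between clinical covariates
and carrier status (covariates are drawn independently), caller-specific
artifact morphology (artifacts are planted keys, not misaligned reads),
locus-realistic positions (background positions are synthetic coordinates),
and any read-level error process. Passing tests therefore demonstrate the
correctness of the triage logic under its stated contracts, not robustness
to upstream caller behaviour.

`paper_scenario()` is the deterministic counterpart: a 107-patient cohort
whose planted content reproduces the published carrier and VUS tables over
a designed-to-fail background (120 calls/patient), with the verification
ledger and curated tiers. Quantities the publication does not print at the
individual level — which patients carry which VUS, individual ages — are
constructed to satisfy every printed aggregate simultaneously (35 VUS
carriers, 19 mismatch-repair-VUS carriers, 9 overlapping the PGV-positive
set, five carriers of the three *MSH6* VUSs, one patient with three *POLE*
VUSs, demographics cross-tab margins) and are documented as synthetic; the
age-based rank-sum comparison is accordingly not treated as a reproducible
surface.

## Numerical and degenerate-input choices

* Fisher's exact test is two-sided under the minimum-likelihood convention
  (sum of tables no more probable than observed, with a 1 + 1e-7 relative
  tolerance on the point-probability comparison); this, and not the mid-p
  variant, reproduces the published age-category p of 0.156. The 2×2 path is
  verified against full hypergeometric enumeration.
* The gender comparison uses the Yates-corrected χ² (continuity correction
  clamped at zero), which reproduces the published 0.697; uncorrected gives
  ≈ 0.54.
* Wilcoxon rank-sum uses exact enumeration when both groups have ≤ 10
  observations without ties, otherwise the tie-corrected normal
  approximation with continuity correction; fully tied data yield p = 1.
* Contingency tables with a zero margin, empty cohorts (undefined
  proportions) and empty groups raise typed errors rather than NaNs.
* Unparseable HGVS suffixes classify as `unknown` with the raw string
  preserved — records are never silently dropped by the parser.
* "Not applicable" levels are excluded from association cross-tabs.
* *EPCAM* is excluded from the mismatch-repair gene set when counting Lynch
  syndrome carriers (its mechanism is *MSH2* silencing by deletion).

## Problem sizes

The default test suite runs the full 107-patient scenario (≈ 13,000
records), 1,000 random 30-record cohorts for the funnel property checks,
the complete 6,144-point criterion lattice, every 2×2 table with total
≤ 40 for the Fisher oracle (≈ 132,000 tables), and 20 seeded 20-patient
synthetic cohorts for planted-variant recovery; these sizes keep each
property exhaustive where the space is enumerable and complete the suite in
a few minutes on one CPU.

## Known limitations

* HGVS support is a deliberate subset (substitutions, del, ins, delins, dup,
  intronic offsets) — the grammar that occurs in panel exports; complex
  alleles parse as `unknown`.
* Splice-candidate detection depends on the supplied exon boundaries; with
  the partial default list, exonic splice-disrupters away from annotated
  junctions are found only via their ClinVar entry.
* The auto-assigner cannot reproduce full manual classifications; cohorts
  without curated evidence will under-call likely-pathogenic missense
  variants (by design, erring toward VUS).
* Combination-dependent classifications (a variant pathogenic only in the
  presence of another heterozygous finding) are outside the combining table
  and must enter as curated evidence.
* Association tests are unadjusted for multiple testing, matching the
  original analysis plan; with four tests at α = 0.05 this is a descriptive,
  not confirmatory, surface.
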