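#' Carrier yield of pathogenic/likely pathogenic variants
#'
#' Number and proportion of distinct patients carrying at least one
#' (verified) pathogenic/likely pathogenic variant.
#'
#' @param n_patients cohort size.
#' @param calls per-patient call data frame with a `sample_id` column
#'   (pre-verification calls, or the `verified` element of
#'   [apply_ledger()]'s result for the post-verification yield).
#' @return list `count`, `proportion`.
#' @export
pgv_yield <- function(n_patients, calls) {
  if (n_patients == 0)
    triage_error("proportion undefined for an empty cohort",
                 "degenerate_cohort_error")
  count <- length(unique(calls$sample_id))
  list(count = count, proportion = count / n_patients)
}

#' Count carriers of verified mismatch-repair PGVs (Lynch syndrome yield)
#'
#' Distinct patients with at least one verified pathogenic/likely pathogenic
#' variant in MLH1, MSH2, MSH6 or PMS2. EPCAM is deliberately not counted in
#' the MMR set here (its mechanism is MSH2 silencing by deletion, not an MMR
#' coding variant).
#'
#' @param verified_calls data frame of verified calls (`gene`, `sample_id`).
#' @return integer count.
#' @export
mmr_carrier_count <- function(verified_calls) {
  length(unique(verified_calls$sample_id[verified_calls$gene %in% mmr_genes()]))
}

#' Per-gene distribution of unique PGVs by tier
#'
#' @param classified classification rows for the unique PGVs (`gene`,
#'   `tier`).
#' @param panel panel definition (genes with zero variants are reported as
#'   zero).
#' @return data frame `gene`, `pathogenic`, `likely_pathogenic`, `total`,
#'   one row per panel gene.
#' @export
per_gene_distribution <- function(classified, panel = default_panel()) {
  out <- data.frame(gene = panel$symbol, stringsAsFactors = FALSE)
  out$pathogenic <- vapply(out$gene, function(g)
    sum(classified$gene == g & classified$tier == "pathogenic"), integer(1))
  out$likely_pathogenic <- vapply(out$gene, function(g)
    sum(classified$gene == g & classified$tier == "likely_pathogenic"),
    integer(1))
  out$total <- out$pathogenic + out$likely_pathogenic
  rownames(out) <- NULL
  out
}

#' Count novel unique PGVs
#'
#' A unique variant is novel when its "reported before?" flag starts with
#' "No" (qualified entries like "No (G>T only)" -- a different allele at the
#' same position was known -- still count as novel). Also reports how many
#' novel variants are in mismatch-repair genes.
#'
#' @param unique_pgvs data frame with `key`, `gene` and either a logical
#'   `novel` column or a character `reported_before` column.
#' @return list `n_novel`, `n_novel_mmr`, `mmr_fraction`.
#' @export
novelty_count <- function(unique_pgvs) {
  novel <- if (!is.null(unique_pgvs$novel)) unique_pgvs$novel
  else startsWith(unique_pgvs$reported_before, "No")
  novel[is.na(novel)] <- FALSE
  u <- !duplicated(unique_pgvs$key)
  n_novel <- sum(novel & u)
  n_mmr <- sum(novel & u & unique_pgvs$gene %in% mmr_genes())
  list(n_novel = n_novel, n_novel_mmr = n_mmr,
       mmr_fraction = if (n_novel > 0) n_mmr / n_novel else NA_real_)
}

#' Concordance between prior tumour IHC and the panel finding
#'
#' A patient's IHC result is concordant with the germline finding when (a) a
#' mismatch-repair protein reported lost matches the gene of the patient's
#' variant, or (b) staining was normal for all MMR proteins ("all positive")
#' and the variant is in a non-MMR gene; otherwise discordant.
#'
#' @param ihc data frame like the packaged `table4_ihc` fixture:
#'   `patient_id`, `ihc_lost` (comma-separated lost proteins or
#'   "all_positive"), `variant_gene`.
#' @return the input with a logical `concordant` column, plus attribute
#'   `n_concordant`.
#' @export
ihc_concordance <- function(ihc) {
  conc <- vapply(seq_len(nrow(ihc)), function(i) {
    lost <- trimws(strsplit(ihc$ihc_lost[i], ",", fixed = TRUE)[[1]])
    g <- ihc$variant_gene[i]
    if (identical(lost, "all_positive")) return(!(g %in% mmr_genes()))
    g %in% lost
  }, logical(1))
  ihc$concordant <- conc
  attr(ihc, "n_concordant") <- sum(conc)
  ihc
}

# ---------------------------------------------------------------------------
# Contingency-table tests (standard tests; base R does the computation)
# ---------------------------------------------------------------------------

check_table <- function(t) {
  t <- as.matrix(t)
  if (any(t < 0) || nrow(t) < 2 || ncol(t) < 2)
    triage_error("contingency table must be at least 2x2 with non-negative counts",
                 "degenerate_table_error")
  if (any(rowSums(t) == 0) || any(colSums(t) == 0))
    triage_error("contingency table has a zero margin", "degenerate_table_error")
  t
}

#' Fisher's exact test (two-sided)
#'
#' Two-sided p-value under the minimum-likelihood convention: the sum of
#' probabilities, over all tables with the observed margins, of tables no
#' more probable than the observed one. r x c tables are supported by exact
#' enumeration for moderate totals.
#'
#' @param t contingency table (matrix, at least 2x2).
#' @return list `p`, `method`.
#' @export
fisher_exact <- function(t) {
  t <- check_table(t)
  list(p = stats::fisher.test(t)$p.value, method = "fisher_exact")
}

#' Pearson chi-squared test with Yates continuity correction (2x2)
#'
#' @param t 2x2 contingency table.
#' @return list `statistic`, `p`, `method`.
#' @export
chi_squared_yates <- function(t) {
  t <- check_table(t)
  if (!all(dim(t) == c(2, 2)))
    triage_error("Yates-corrected chi-squared requires a 2x2 table",
                 "degenerate_table_error")
  expected <- outer(rowSums(t), colSums(t)) / sum(t)
  if (any(expected == 0))
    triage_error("zero expected cell count", "degenerate_table_error")
  res <- suppressWarnings(stats::chisq.test(t, correct = TRUE))
  list(statistic = unname(res$statistic), p = res$p.value,
       method = "chi_squared_yates")
}

#' Wilcoxon rank-sum test (two-sided)
#'
#' Exact enumeration when both groups have at most 10 observations and no
#' ties; otherwise the normal approximation with tie correction and
#' continuity correction.
#'
#' @param x,y numeric value vectors, both non-empty.
#' @return list `p`, `method`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0 || length(y) == 0)
    triage_error("both groups must be non-empty", "degenerate_group_error")
  exact <- length(x) <= 10 && length(y) <= 10 && !anyDuplicated(c(x, y))
  res <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                             correct = TRUE))
  p <- res$p.value
  # fully tied data: the rank distribution is degenerate, no evidence of shift
  if (is.na(p) && length(unique(c(x, y))) == 1L) p <- 1
  list(p = p,
       method = if (exact) "wilcoxon_exact" else "wilcoxon_normal_approx")
}

# ---------------------------------------------------------------------------
# Cohort summary
# ---------------------------------------------------------------------------

#' Association tests of mutation status against clinical variables
#'
#' Builds the positive/negative cross-tabs from an aggregate table in the
#' shape of the packaged `table2_aggregates` fixture and runs the test used
#' for each variable: Fisher's exact test for the age category (sparse
#' cells), the Yates-corrected chi-squared for gender. "Not applicable"
#' levels are excluded from association tables.
#'
#' @param aggregates data frame `variable`, `level`, `positive`, `negative`.
#' @return data frame `variable`, `statistic`, `p`, `method`, `significant`
#'   (threshold 0.05).
#' @export
association_tests <- function(aggregates) {
  tab_for <- function(var) {
    rows <- aggregates[aggregates$variable == var &
                         aggregates$level != "not_applicable", , drop = FALSE]
    m <- as.matrix(rows[, c("positive", "negative")])
    rownames(m) <- rows$level
    m
  }
  age <- fisher_exact(t(tab_for("categorical_age")))
  gender <- chi_squared_yates(t(tab_for("gender")))
  loc <- fisher_exact(t(tab_for("localization")[c("colon", "rectum", "both"), ]))
  side <- fisher_exact(t(tab_for("sidedness")[c("right", "left", "both"), ]))
  out <- data.frame(
    variable = c("categorical_age", "gender", "localization", "sidedness"),
    statistic = c(NA, gender$statistic, NA, NA),
    p = c(age$p, gender$p, loc$p, side$p),
    method = c(age$method, gender$method, loc$method, side$method),
    stringsAsFactors = FALSE)
  out$significant <- out$p < 0.05
  out
}

#' Build the full cohort summary
#'
#' Assembles every summary surface of the analysis: pre/post-verification
#' carrier yields, per-gene distribution of unique PGVs, novelty, the
#' mismatch-repair (Lynch syndrome) carrier count, the VUS surface and its
#' overlap with PGV carriers, patient resolution status, and (when an
#' aggregate demographics table is supplied) the association tests with
#' their 0.05 significance annotation.
#'
#' @param n_patients cohort size.
#' @param pgv_calls pre-verification per-patient PGV calls (`key`,
#'   `sample_id`, `gene`, `cdna`, optionally `tier`).
#' @param verified a `verified_calls` object from [apply_ledger()].
#' @param classified classification of the unique PGVs (for the per-gene
#'   split); needs `key`, `gene`, `tier`, optionally novelty columns.
#' @param vus_report a `funnel_report` from [run_vus_funnel()], or `NULL`.
#' @param aggregates optional demographics aggregate table for
#'   [association_tests()].
#' @param panel panel definition.
#' @return list of class `cohort_summary`.
#' @export
build_summary <- function(n_patients, pgv_calls, verified, classified,
                          vus_report = NULL, aggregates = NULL,
                          panel = default_panel()) {
  pre <- pgv_yield(n_patients, pgv_calls)
  post <- pgv_yield(n_patients, verified$verified)
  unresolved_only <- setdiff(unique(pgv_calls$sample_id),
                             unique(verified$verified$sample_id))
  summary <- list(
    n_patients = n_patients,
    pre_verification = list(carriers = pre$count,
                            percent = round(100 * pre$proportion, 2)),
    post_verification = list(carriers = post$count,
                             percent = round(100 * post$proportion, 2)),
    unresolved_former_carriers = sort(unresolved_only),
    n_unique_pgvs = length(unique(pgv_calls$key)),
    per_gene = per_gene_distribution(classified, panel),
    mmr_carriers = mmr_carrier_count(verified$verified),
    mmr_percent = round(100 * mmr_carrier_count(verified$verified) /
                          n_patients, 2))
  if (!is.null(classified$novel) || !is.null(classified$reported_before))
    summary$novelty <- novelty_count(classified)
  if (!is.null(vus_report)) {
    summary$vus <- list(
      n_unique = vus_report$n_unique_vus,
      n_unique_mmr = length(vus_report$mmr_unique),
      n_carriers = length(vus_report$vus_carriers),
      n_carriers_with_pgv = length(vus_report$carriers_with_pgv),
      n_carriers_without_pgv = length(vus_report$carriers_without_pgv))
  }
  if (!is.null(aggregates)) {
    summary$association <- association_tests(aggregates)
    summary$significance_threshold <- 0.05
  }
  class(summary) <- "cohort_summary"
  summary
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d patients\n", x$n_patients))
  cat(sprintf("  PGV carriers: %d (%.2f%%) pre-verification; %d (%.2f%%) verified\n",
              x$pre_verification$carriers, x$pre_verification$percent,
              x$post_verification$carriers, x$post_verification$percent))
  cat(sprintf("  unique PGVs: %d; MMR (Lynch) carriers: %d (%.2f%%)\n",
              x$n_unique_pgvs, x$mmr_carriers, x$mmr_percent))
  if (!is.null(x$novelty))
    cat(sprintf("  novel unique PGVs: %d (%d in MMR genes)\n",
                x$novelty$n_novel, x$novelty$n_novel_mmr))
  if (!is.null(x$vus))
    cat(sprintf("  unique VUSs: %d (%d in MMR genes), %d carriers (%d also carry a PGV)\n",
                x$vus$n_unique, x$vus$n_unique_mmr, x$vus$n_carriers,
                x$vus$n_carriers_with_pgv))
  invisible(x)
}

#' Serialize a cohort summary to JSON (and the per-gene table to TSV)
#'
#' @param summary a `cohort_summary`.
#' @param json_path,tsv_path output paths (`NULL` to skip).
#' @return the summary, invisibly.
#' @export
write_summary <- function(summary, json_path = NULL, tsv_path = NULL) {
  if (!is.null(json_path))
    jsonlite::write_json(unclass(summary), json_path, auto_unbox = TRUE,
                         digits = NA)
  if (!is.null(tsv_path)) write_tsv(summary$per_gene, tsv_path)
  invisible(summary)
}

#' Read back a JSON cohort summary
#'
#' @param json_path path written by [write_summary()].
#' @return list (per-gene table as a data frame).
#' @export
read_summary <- function(json_path) {
  jsonlite::read_json(json_path, simplifyVector = TRUE)
}
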