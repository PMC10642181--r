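#' Filter funnel configuration
#'
#' Tunable thresholds of the variant-prioritisation funnel. Defaults encode
#' the published protocol: retain rare variants (MAF < 0.05; a missing MAF is
#' treated as "rare, unknown" and retained), exclude calls covered by 30
#' reads or fewer (retain depth > `depth_min`), keep exonic and flanking
#' variants (an intronic offset within `flank_bp` bases counts as flanking;
#' the canonical +/-1/2 dinucleotide always does), keep ClinVar categories
#' other than benign/likely benign, and flag recurrent indel artifacts seen
#' in more than `artifact_sample_fraction` of samples ("multiple samples" is
#' not quantified upstream, so the fraction is configurable).
#' `synonymous_rescue` retains synonymous calls that ClinVar marks
#' pathogenic-tier or that sit at an annotated exon boundary — the manual
#' re-inspection that recovered a synonymous-but-splice-disrupting call,
#' made deterministic.
#'
#' @param maf_max retain `maf < maf_max` or missing (default 0.05).
#' @param depth_min retain `depth > depth_min` (default 30).
#' @param flank_bp intronic offset still counted as flanking (default 20).
#' @param clinvar_keep ClinVar categories retained by the ClinVar stage.
#' @param artifact_sample_fraction indel recurrence fraction above which a
#'   call is flagged as an alignment artifact (default 0.2).
#' @param synonymous_rescue logical (default TRUE).
#' @return list of class `filter_config`.
#' @export
filter_config <- function(maf_max = 0.05, depth_min = 30L, flank_bp = 20L,
                          clinvar_keep = c("pathogenic", "likely_pathogenic",
                                           "path_or_lp", "uncertain",
                                           "conflicting", "no_entry"),
                          artifact_sample_fraction = 0.2,
                          synonymous_rescue = TRUE) {
  stopifnot(maf_max > 0, maf_max <= 1, depth_min >= 0, flank_bp >= 0,
            artifact_sample_fraction > 0)
  structure(list(maf_max = maf_max, depth_min = as.integer(depth_min),
                 flank_bp = as.integer(flank_bp), clinvar_keep = clinvar_keep,
                 artifact_sample_fraction = artifact_sample_fraction,
                 synonymous_rescue = isTRUE(synonymous_rescue)),
            class = "filter_config")
}

pathogenic_tier_clinvar <- c("pathogenic", "likely_pathogenic", "path_or_lp")

# ---------------------------------------------------------------------------
# Individual stages (each takes and returns an annotation record data frame)
# ---------------------------------------------------------------------------

#' Funnel stages
#'
#' Each stage is an individually reportable filter over annotation records:
#' `stage_pass()` keeps caller-PASS records; `stage_functional()` removes
#' synonymous calls (unless rescued as ClinVar-pathogenic or
#' splice-candidate) and restricts location to exonic/flanking (an intronic
#' offset within `cfg$flank_bp` counts as flanking); `stage_maf()` keeps rare
#' or frequency-unknown calls; `stage_depth()` keeps calls covered by more
#' than `cfg$depth_min` reads; `stage_clinvar()` keeps the retained ClinVar
#' categories.
#'
#' @param records annotation record data frame.
#' @param cfg a [filter_config()].
#' @return filtered record data frame.
#' @name funnel_stages
NULL

#' @rdname funnel_stages
#' @export
stage_pass <- function(records) records[records$filter_status == "PASS", , drop = FALSE]

#' @rdname funnel_stages
#' @export
stage_functional <- function(records, cfg = filter_config()) {
  syn <- records$kind == "synonymous"
  rescued <- cfg$synonymous_rescue &
    (records$clinvar %in% pathogenic_tier_clinvar | records$splice_candidate)
  keep_fun <- !syn | rescued
  flanking <- records$location == "flanking" |
    (records$location == "intronic" & !is.na(records$intron_offset) &
       abs(records$intron_offset) <= cfg$flank_bp)
  keep_loc <- records$location == "exonic" | flanking
  records[keep_fun & keep_loc, , drop = FALSE]
}

#' @rdname funnel_stages
#' @export
stage_maf <- function(records, cfg = filter_config()) {
  records[is.na(records$maf) | records$maf < cfg$maf_max, , drop = FALSE]
}

#' @rdname funnel_stages
#' @export
stage_depth <- function(records, cfg = filter_config()) {
  records[records$depth > cfg$depth_min, , drop = FALSE]
}

#' @rdname funnel_stages
#' @export
stage_clinvar <- function(records, cfg = filter_config()) {
  records[records$clinvar %in% cfg$clinvar_keep, , drop = FALSE]
}

#' Flag recurrent indel artifacts across the cohort
#'
#' Random insertion/deletion calls recurring around the same position in many
#' samples despite high coverage are alignment artifacts. This stage
#' deterministically replaces their manual genome-browser inspection: an
#' indel variant key carried by more than `cfg$artifact_sample_fraction` of
#' the cohort's samples is flagged. Substitutions are never flagged.
#'
#' @param records annotation record data frame (cohort-wide view).
#' @param n_samples total number of samples in the cohort; defaults to the
#'   number of distinct `sample_id`s present in `records`.
#' @param cfg a [filter_config()].
#' @return `records` with a logical `artifact` column added.
#' @export
flag_artifacts <- function(records, n_samples = length(unique(records$sample_id)),
                           cfg = filter_config()) {
  records$artifact <- logical(nrow(records))
  if (nrow(records) == 0 || n_samples == 0) return(records)
  is_indel <- records$kind %in% c("frameshift", "inframe_indel") |
    grepl("del|ins|dup", records$cdna)
  carriers <- tapply(records$sample_id, records$key,
                     function(s) length(unique(s)))
  frac <- carriers[records$key] / n_samples
  records$artifact <- is_indel & as.vector(frac) > cfg$artifact_sample_fraction
  records
}

#' Collapse records to unique variants with their carriers
#'
#' One row per variant key, with the carrier sample list and carrier count;
#' representative annotation fields are taken from the first record of each
#' key (record-level provenance is preserved through the `records` attribute
#' of the funnel report, not here).
#'
#' @param records annotation record data frame.
#' @return data frame with one row per unique variant: `key`, `gene`, `cdna`,
#'   `protein`, `kind`, `clinvar`, `maf`, `n_carriers`, `carriers`
#'   (comma-separated sample ids).
#' @export
dedupe <- function(records) {
  if (nrow(records) == 0)
    return(data.frame(key = character(), gene = character(),
                      cdna = character(), protein = character(),
                      kind = character(), clinvar = character(),
                      maf = numeric(), n_carriers = integer(),
                      carriers = character(), stringsAsFactors = FALSE))
  keys <- unique(records$key)
  first <- records[match(keys, records$key), , drop = FALSE]
  carriers <- lapply(keys, function(k)
    sort(unique(records$sample_id[records$key == k])))
  out <- data.frame(key = keys, gene = first$gene, cdna = first$cdna,
                    protein = first$protein, kind = first$kind,
                    clinvar = first$clinvar, maf = first$maf,
                    n_carriers = lengths(carriers),
                    carriers = vapply(carriers, paste, "", collapse = ","),
                    stringsAsFactors = FALSE, row.names = NULL)
  for (extra in intersect(c("intron_offset", "splice_candidate", "depth",
                            "cdna_position", "cdna_end", "sift", "polyphen",
                            "grantham", "fathmm"), names(first)))
    out[[extra]] <- first[[extra]]
  out
}

new_funnel_report <- function(stages, records, unique_variants, extra = list()) {
  stopifnot(all(diff(stages$n_records) <= 0))
  structure(c(list(stages = stages, records = records,
                   unique_variants = unique_variants), extra),
            class = "funnel_report")
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("<funnel_report>\n")
  print(x$stages, row.names = FALSE)
  cat(sprintf("final: %d records, %d unique variants\n",
              nrow(x$records), nrow(x$unique_variants)))
  invisible(x)
}

#' Run the pathogenic-variant prioritisation funnel
#'
#' Applies the published filter cascade in order: caller PASS status;
#' functional class and location; population allele frequency; ClinVar
#' category; recurrent-indel artifact flag; depth of coverage; and
#' deduplication to unique variants. Per-stage retained record counts and
#' retained unique-variant counts are recorded; counts are non-increasing by
#' construction.
#'
#' @param records annotation record data frame (the whole cohort).
#' @param cfg a [filter_config()].
#' @param n_samples cohort size for the artifact-recurrence denominator.
#' @return a `funnel_report`: `stages` (stage, n_records, n_unique),
#'   `records` (retained records), `unique_variants` (deduped set with
#'   carriers), and `artifacts` (records flagged and excluded as recurrent
#'   indel artifacts, preserved for the report).
#' @export
run_pgv_funnel <- function(records, cfg = filter_config(),
                           n_samples = length(unique(records$sample_id))) {
  stages <- list()
  note <- function(name, recs) {
    stages[[length(stages) + 1L]] <<- data.frame(
      stage = name, n_records = nrow(recs),
      n_unique = length(unique(recs$key)), stringsAsFactors = FALSE)
    recs
  }
  r <- note("input", records)
  r <- note("pass", stage_pass(r))
  r <- note("functional", stage_functional(r, cfg))
  r <- note("maf", stage_maf(r, cfg))
  r <- note("clinvar", stage_clinvar(r, cfg))
  r <- flag_artifacts(r, n_samples, cfg)
  artifacts <- r[r$artifact, , drop = FALSE]
  r <- note("artifact", r[!r$artifact, , drop = FALSE])
  r <- note("depth", stage_depth(r, cfg))
  uv <- dedupe(r)
  new_funnel_report(do.call(rbind, stages), r, uv,
                    extra = list(artifacts = artifacts))
}

#' Run the VUS funnel
#'
#' The parallel cascade for variants of uncertain significance: select
#' ClinVar "uncertain significance" calls, drop low-coverage calls (depth
#' <= `cfg$depth_min`), restrict to exonic non-synonymous calls, deduplicate,
#' and keep rare/frequency-unknown variants. The stage order follows the
#' published narrative so per-stage counts remain comparable to the printed
#' funnel. Also reports carriers with at least one retained VUS, partitioned
#' by whether they additionally carry a prioritised pathogenic/likely
#' pathogenic variant.
#'
#' @param records annotation record data frame (the whole cohort).
#' @param cfg a [filter_config()].
#' @param pgv_positive character vector of sample ids already carrying a
#'   prioritised pathogenic/likely pathogenic variant (for the overlap
#'   partition; may be empty).
#' @return a `funnel_report` with extra elements `n_unique_vus`,
#'   `vus_carriers` (sample ids), `carriers_with_pgv`,
#'   `carriers_without_pgv`, and `mmr_unique` (unique VUS keys in mismatch
#'   repair genes).
#' @export
run_vus_funnel <- function(records, cfg = filter_config(),
                           pgv_positive = character()) {
  stages <- list()
  note <- function(name, recs) {
    stages[[length(stages) + 1L]] <<- data.frame(
      stage = name, n_records = nrow(recs),
      n_unique = length(unique(recs$key)), stringsAsFactors = FALSE)
    recs
  }
  r <- note("uncertain", records[records$clinvar == "uncertain", , drop = FALSE])
  r <- note("depth", stage_depth(r, cfg))
  r <- note("exonic_nonsyn",
            r[r$location == "exonic" & r$kind != "synonymous", , drop = FALSE])
  r <- note("maf", stage_maf(r, cfg))
  uv <- dedupe(r)
  carriers <- sort(unique(r$sample_id))
  new_funnel_report(do.call(rbind, stages), r, uv, extra = list(
    n_unique_vus = nrow(uv),
    vus_carriers = carriers,
    carriers_with_pgv = intersect(carriers, pgv_positive),
    carriers_without_pgv = setdiff(carriers, pgv_positive),
    mmr_unique = uv$key[uv$gene %in% mmr_genes()]))
}

#' Serialize a funnel report
#'
#' @param report a `funnel_report`.
#' @param json_path,tsv_path output paths (either may be `NULL` to skip).
#' @return invisibly, the list serialized to JSON.
#' @export
write_funnel_report <- function(report, json_path = NULL, tsv_path = NULL) {
  out <- list(stages = report$stages,
              n_final_records = nrow(report$records),
              n_unique_variants = nrow(report$unique_variants))
  if (!is.null(report$n_unique_vus)) out$n_unique_vus <- report$n_unique_vus
  if (!is.null(json_path))
    jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(tsv_path)) write_tsv(report$stages, tsv_path)
  invisible(out)
}
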