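#' Pseudogene homology regions
#'
#' Regions of a panel gene's coding sequence that are (near-)identical to a
#' pseudogene, where short-read calls cannot be attributed to the functional
#' locus without gene-specific verification. The shipped default covers the
#' 3' portion of PMS2 (c.1145-2589, exons 11-15 of NM_000535.7), the segment
#' shared with the pseudogene PMS2CL; the exact boundary is configuration,
#' not hard-coded biology.
#'
#' @param path TSV with columns `gene`, `cdna_start`, `cdna_end`,
#'   `pseudogene`; defaults to the packaged PMS2/PMS2CL definition.
#' @return data frame of homology regions.
#' @export
read_homology_regions <- function(path = system.file("extdata",
                                                     "homology_regions.tsv",
                                                     package = "crctriage")) {
  df <- read_tsv(path)
  stopifnot(all(df$cdna_start <= df$cdna_end))
  df
}

#' Does a variant need gene-specific verification?
#'
#' `TRUE` iff the variant's coding span intersects a homology region for its
#' gene, i.e. a standard short-read call cannot distinguish the gene from its
#' pseudogene at that position.
#'
#' @param gene gene symbol.
#' @param v an `hgvs_variant` (or cDNA string, parsed on the fly).
#' @param regions homology region data frame (see
#'   [read_homology_regions()]).
#' @return logical.
#' @export
needs_gene_specific_verification <- function(gene, v,
                                             regions = read_homology_regions()) {
  if (is.character(v)) v <- parse_cdna(v)
  r <- regions[regions$gene == gene, , drop = FALSE]
  if (nrow(r) == 0) return(FALSE)
  lo <- v$cdna_position
  hi <- if (!is.na(v$cdna_end)) v$cdna_end else lo
  if (is.na(lo)) return(FALSE)
  any(lo <= r$cdna_end & hi >= r$cdna_start)
}

#' Read a verification ledger
#'
#' Per-(variant, sample) record of orthogonal confirmation: Sanger and/or
#' gene-specific long-range PCR. Statuses: `confirmed_present`,
#' `confirmed_absent`, `unverified`.
#'
#' @param path TSV with columns `gene`, `cdna`, `sample_id`, `status`;
#'   defaults to the packaged ledger of the published verification outcome.
#' @return data frame with a `key` column added.
#' @export
read_ledger <- function(path = system.file("extdata",
                                           "verification_ledger.tsv",
                                           package = "crctriage")) {
  df <- read_tsv(path)
  if (!all(df$status %in% c("confirmed_present", "confirmed_absent",
                            "unverified")))
    triage_error("ledger status must be confirmed_present/confirmed_absent/unverified",
                 "validation_error")
  df$sample_id <- as.character(df$sample_id)
  df$key <- variant_key(df$gene, df$cdna)
  if (anyDuplicated(df[, c("key", "sample_id")]))
    triage_error("at most one ledger status per (variant, sample)",
                 "validation_error")
  df
}

#' Apply a verification ledger to per-patient PGV calls
#'
#' Removes calls the ledger marks `confirmed_absent` (the variant was shown
#' not to be present in the functional gene -- e.g. a pseudogene-origin
#' call). Calls that need gene-specific verification (their span intersects
#' a homology region) but have no `confirmed_present` ledger entry are also
#' withheld from the verified set and reported separately: an unverified call
#' in a pseudogene-shadowed region is never counted as a verified finding.
#' All other calls are retained. The operation never adds calls and is
#' idempotent.
#'
#' @param calls data frame of per-patient PGV calls with columns `key`,
#'   `sample_id`, `gene`, `cdna` (one row per variant per carrier).
#' @param ledger ledger data frame (see [read_ledger()]); may have zero
#'   rows.
#' @param regions homology regions (see [read_homology_regions()]).
#' @return list of class `verified_calls`: `verified` (retained calls),
#'   `removed` (confirmed-absent calls), `unverified` (homology-region calls
#'   without confirmation), each a data frame with a `verification` column.
#' @export
apply_ledger <- function(calls, ledger = NULL, regions = read_homology_regions()) {
  if (is.null(ledger))
    ledger <- data.frame(key = character(), sample_id = character(),
                         status = character(), stringsAsFactors = FALSE)
  stray <- !paste(ledger$key, ledger$sample_id) %in%
    paste(calls$key, calls$sample_id)
  if (any(stray))
    warning(sprintf("ledger entr%s for call(s) never made: %s",
                    if (sum(stray) > 1) "ies" else "y",
                    paste(ledger$key[stray], ledger$sample_id[stray],
                          sep = "@", collapse = ", ")))
  if (nrow(calls) == 0)
    return(structure(list(verified = calls, removed = calls,
                          unverified = calls), class = "verified_calls"))
  status <- ledger$status[match(paste(calls$key, calls$sample_id),
                                paste(ledger$key, ledger$sample_id))]
  status[is.na(status)] <- "unverified"
  needs <- vapply(seq_len(nrow(calls)), function(i)
    needs_gene_specific_verification(calls$gene[i], calls$cdna[i], regions),
    logical(1))
  removed <- status == "confirmed_absent"
  withheld <- !removed & needs & status != "confirmed_present"
  verified <- !removed & !withheld
  out <- list(
    verified = transform(calls[verified, , drop = FALSE],
                         verification = status[verified]),
    removed = transform(calls[removed, , drop = FALSE],
                        verification = status[removed]),
    unverified = transform(calls[withheld, , drop = FALSE],
                           verification = rep("unverified", sum(withheld))))
  structure(out, class = "verified_calls")
}

#' @export
print.verified_calls <- function(x, ...) {
  cat(sprintf("<verified_calls> %d verified, %d removed (confirmed absent), %d unverified in homology regions\n",
              nrow(x$verified), nrow(x$removed), nrow(x$unverified)))
  invisible(x)
}

#' Resolve patient status after verification
#'
#' A patient is `resolved` iff at least one verified pathogenic/likely
#' pathogenic call remains; patients whose only calls were removed or
#' withheld by verification -- and patients with no PGV call at all --
#' are `unresolved`.
#'
#' @param patient_ids all patient ids in the cohort.
#' @param verified a `verified_calls` object from [apply_ledger()].
#' @return data frame `patient_id`, `status` ("resolved"/"unresolved").
#' @export
resolve_patients <- function(patient_ids, verified) {
  status <- ifelse(patient_ids %in% verified$verified$sample_id,
                   "resolved", "unresolved")
  data.frame(patient_id = as.character(patient_ids), status = status,
             stringsAsFactors = FALSE)
}

#' Expand per-variant carrier rows into per-patient calls
#'
#' Helper turning a deduped unique-variant table (with its comma-separated
#' `carriers` column) back into one row per (variant, carrier), the shape
#' [apply_ledger()] works on.
#'
#' @param unique_variants data frame with `key`, `gene`, `cdna`, `carriers`.
#' @param tiers optional classification (from [classify_cohort()]) used to
#'   keep only pathogenic/likely pathogenic variants and attach the tier.
#' @return data frame with columns `key`, `sample_id`, `gene`, `cdna` (and
#'   `tier` if supplied).
#' @export
expand_carriers <- function(unique_variants, tiers = NULL) {
  if (!is.null(tiers)) {
    unique_variants <- merge(unique_variants,
                             tiers[, c("key", "tier")], by = "key")
    unique_variants <- unique_variants[
      unique_variants$tier %in% c("pathogenic", "likely_pathogenic"), ,
      drop = FALSE]
  }
  if (nrow(unique_variants) == 0)
    return(data.frame(key = character(), sample_id = character(),
                      gene = character(), cdna = character(),
                      tier = character(), stringsAsFactors = FALSE))
  reps <- strsplit(unique_variants$carriers, ",", fixed = TRUE)
  idx <- rep(seq_len(nrow(unique_variants)), lengths(reps))
  out <- data.frame(key = unique_variants$key[idx],
                    sample_id = unlist(reps),
                    gene = unique_variants$gene[idx],
                    cdna = unique_variants$cdna[idx],
                    stringsAsFactors = FALSE)
  if (!is.null(tiers)) out$tier <- unique_variants$tier[idx]
  rownames(out) <- NULL
  out
}
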