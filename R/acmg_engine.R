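#' The 28 ACMG/AMP evidence codes and their native strengths
#'
#' @return data frame with `code` and `native_strength` for the 28 codes:
#'   PVS1; PS1-PS4; PM1-PM6; PP1-PP5; BA1; BS1-BS4; BP1-BP7.
#' @export
acmg_codes <- function() {
  data.frame(
    code = c("PVS1", paste0("PS", 1:4), paste0("PM", 1:6), paste0("PP", 1:5),
             "BA1", paste0("BS", 1:4), paste0("BP", 1:7)),
    native_strength = c("very_strong", rep("strong", 4), rep("moderate", 6),
                        rep("supporting", 5), "stand_alone", rep("strong", 4),
                        rep("supporting", 7)),
    stringsAsFactors = FALSE)
}

acmg_strengths <- c("stand_alone", "very_strong", "strong", "moderate",
                    "supporting")

#' Build an evidence set from criterion codes
#'
#' Codes may carry a strength override as `CODE:strength` (e.g.
#' `"PS4:moderate"`); otherwise the code's native strength applies. The
#' verdict of [acmg_combine()] counts criteria at their effective strengths.
#'
#' @param codes character vector of codes, optionally with `:strength`
#'   suffixes; duplicates (by code) are an error.
#' @return data frame of class `evidence_set` with columns `code`,
#'   `strength`, `side` ("pathogenic"/"benign").
#' @export
evidence_set <- function(codes = character()) {
  codes <- codes[!is.na(codes) & codes != ""]
  if (length(codes) == 0)
    return(structure(data.frame(code = character(), strength = character(),
                                side = character(), stringsAsFactors = FALSE),
                     class = c("evidence_set", "data.frame")))
  parts <- strsplit(codes, ":", fixed = TRUE)
  code <- toupper(vapply(parts, `[[`, "", 1L))
  override <- vapply(parts, function(p) if (length(p) > 1) tolower(p[2]) else
    NA_character_, "")
  tab <- acmg_codes()
  bad <- !code %in% tab$code
  if (any(bad))
    triage_error(sprintf("unknown ACMG code(s): %s",
                         paste(unique(code[bad]), collapse = ", ")),
                 "validation_error")
  if (anyDuplicated(code))
    triage_error("duplicate ACMG codes in evidence set", "validation_error")
  if (any(!is.na(override) & !override %in% acmg_strengths))
    triage_error("invalid strength override", "validation_error")
  strength <- ifelse(is.na(override),
                     tab$native_strength[match(code, tab$code)], override)
  structure(data.frame(code = code, strength = strength,
                       side = ifelse(startsWith(code, "B"), "benign",
                                     "pathogenic"),
                       stringsAsFactors = FALSE),
            class = c("evidence_set", "data.frame"))
}

#' Combine ACMG evidence into a five-tier verdict
#'
#' Implements the ACMG/AMP combining rules over effective strengths.
#' Pathogenic requires one of: very-strong evidence (PVS1) plus >=1 strong,
#' >=2 moderate, 1 moderate + 1 supporting, or >=2 supporting; >=2 strong;
#' or 1 strong plus >=3 moderate, 2 moderate + >=2 supporting, or 1 moderate
#' + >=4 supporting. Likely pathogenic: very-strong + 1 moderate; 1 strong +
#' 1-2 moderate; 1 strong + >=2 supporting; >=3 moderate; 2 moderate + >=2
#' supporting; or 1 moderate + >=4 supporting. Benign: stand-alone (BA1) or
#' >=2 benign-strong. Likely benign: 1 benign-strong + 1 benign-supporting,
#' or >=2 benign-supporting. If rules fire on both sides the evidence is
#' contradictory and the verdict is uncertain significance with
#' `conflict = TRUE`; with no rule fired the verdict is uncertain
#' significance. Note the strict reading: PVS1 alone does not reach likely
#' pathogenic.
#'
#' @param evidence an `evidence_set` (or character vector of codes passed to
#'   [evidence_set()]).
#' @return list of class `acmg_classification`: `tier` (one of "pathogenic",
#'   "likely_pathogenic", "vus", "likely_benign", "benign"), `fired_rule`
#'   (text naming the matched clause), `conflict` (logical).
#' @export
acmg_combine <- function(evidence) {
  if (!inherits(evidence, "evidence_set")) evidence <- evidence_set(evidence)
  pv <- sum(evidence$side == "pathogenic" & evidence$strength == "very_strong")
  ps <- sum(evidence$side == "pathogenic" & evidence$strength == "strong")
  pm <- sum(evidence$side == "pathogenic" & evidence$strength == "moderate")
  pp <- sum(evidence$side == "pathogenic" & evidence$strength == "supporting")
  ba <- sum(evidence$side == "benign" & evidence$strength == "stand_alone")
  bs <- sum(evidence$side == "benign" & evidence$strength == "strong")
  bp <- sum(evidence$side == "benign" & evidence$strength == "supporting")

  path_rule <- if (pv >= 1 && (ps >= 1 || pm >= 2 || (pm == 1 && pp == 1) ||
                               pp >= 2)) "P: PVS + support"
  else if (ps >= 2) "P: >=2 strong"
  else if (ps == 1 && (pm >= 3 || (pm == 2 && pp >= 2) ||
                       (pm == 1 && pp >= 4))) "P: strong + moderate/supporting"
  else NULL

  lp_rule <- if (pv >= 1 && pm == 1) "LP: PVS + 1 moderate"
  else if (ps == 1 && pm >= 1 && pm <= 2) "LP: 1 strong + 1-2 moderate"
  else if (ps == 1 && pp >= 2) "LP: 1 strong + >=2 supporting"
  else if (pm >= 3) "LP: >=3 moderate"
  else if (pm == 2 && pp >= 2) "LP: 2 moderate + >=2 supporting"
  else if (pm == 1 && pp >= 4) "LP: 1 moderate + >=4 supporting"
  else NULL

  ben_rule <- if (ba >= 1) "B: stand-alone"
  else if (bs >= 2) "B: >=2 strong"
  else NULL

  lb_rule <- if (bs == 1 && bp == 1) "LB: 1 strong + 1 supporting"
  else if (bp >= 2) "LB: >=2 supporting"
  else NULL

  p_side <- path_rule %||% lp_rule
  b_side <- ben_rule %||% lb_rule
  if (!is.null(p_side) && !is.null(b_side)) {
    res <- list(tier = "vus",
                fired_rule = sprintf("conflict (%s vs %s)", p_side, b_side),
                conflict = TRUE)
  } else if (!is.null(path_rule)) {
    res <- list(tier = "pathogenic", fired_rule = path_rule, conflict = FALSE)
  } else if (!is.null(lp_rule)) {
    res <- list(tier = "likely_pathogenic", fired_rule = lp_rule,
                conflict = FALSE)
  } else if (!is.null(ben_rule)) {
    res <- list(tier = "benign", fired_rule = ben_rule, conflict = FALSE)
  } else if (!is.null(lb_rule)) {
    res <- list(tier = "likely_benign", fired_rule = lb_rule, conflict = FALSE)
  } else {
    res <- list(tier = "vus", fired_rule = "no rule fired", conflict = FALSE)
  }
  class(res) <- "acmg_classification"
  res
}

#' @export
print.acmg_classification <- function(x, ...) {
  cat(sprintf("<acmg> %s [%s]%s\n", x$tier, x$fired_rule,
              if (x$conflict) " (conflicting evidence)" else ""))
  invisible(x)
}

#' Automatic assignment of computable ACMG criteria
#'
#' A deliberately conservative assigner restricted to criteria computable
#' from the annotation record alone: PVS1 (null variant -- nonsense,
#' frameshift, or canonical +/-1/2 splice -- in a gene where loss of function
#' is the disease mechanism); PM2 (absent/very rare: MAF missing or below
#' `pm2_max`); PM4 (in-frame indel, protein-length change); BA1 (MAF > 0.05,
#' stand-alone benign); BS1 (MAF above `bs1_max` but not BA1); BP7
#' (synonymous, no splice candidacy, computational evidence benign); PP3/BP4
#' (at least 3 of the 4 prediction calls concordant). Criteria requiring
#' database lookups or segregation data (PS1, PM5, PP1, ...) are never
#' auto-assigned; they enter through curated evidence.
#'
#' @param record one annotation record (single data frame row).
#' @param gene_info the record's panel row (for `lof_mechanism`).
#' @param pm2_max MAF threshold for PM2 (default 1e-4).
#' @param bs1_max MAF threshold for BS1 (default 1e-3).
#' @return an `evidence_set`.
#' @export
auto_assign <- function(record, gene_info, pm2_max = 1e-4, bs1_max = 1e-3) {
  fld <- function(name, default = NA) {
    v <- record[[name]]
    if (is.null(v) || length(v) == 0) default else v[1]
  }
  codes <- character()
  kind <- fld("kind", "unknown")
  offset <- fld("intron_offset", NA_integer_)
  null_variant <- kind %in% c("nonsense", "frameshift") ||
    (kind == "splice_site" && !is.na(offset) && abs(offset) <= 2)
  if (null_variant && isTRUE(gene_info$lof_mechanism)) codes <- c(codes, "PVS1")
  maf <- fld("maf", NA_real_)
  if (is.na(maf) || maf < pm2_max) codes <- c(codes, "PM2")
  if (kind == "inframe_indel") codes <- c(codes, "PM4")
  if (!is.na(maf) && maf > 0.05) codes <- c(codes, "BA1")
  else if (!is.na(maf) && maf > bs1_max) codes <- c(codes, "BS1")

  preds <- tolower(c(fld("sift", NA_character_), fld("polyphen", NA_character_),
                     fld("grantham", NA_character_), fld("fathmm", NA_character_)))
  n_del <- sum(preds %in% "deleterious")
  n_ben <- sum(preds %in% "tolerated")
  if (n_del >= 3) codes <- c(codes, "PP3")
  if (n_ben >= 3) codes <- c(codes, "BP4")
  if (kind == "synonymous" && !isTRUE(fld("splice_candidate", FALSE)) &&
      n_ben >= 3) codes <- c(codes, "BP7")
  evidence_set(codes)
}

#' Read a curated-evidence file
#'
#' @param path TSV with columns `gene`, `cdna`, `criteria`
#'   (semicolon-separated codes with optional `:strength` overrides; may be
#'   empty) and optional `tier` (final tier override).
#' @return data frame with a `key` column added.
#' @export
read_curated_evidence <- function(path) {
  df <- read_tsv(path)
  df$key <- variant_key(df$gene, df$cdna)
  if (is.null(df$criteria)) df$criteria <- ""
  df$criteria[is.na(df$criteria)] <- ""
  df
}

#' Classify a set of unique variants
#'
#' For every unique variant, merges curated evidence (criterion codes and/or
#' a final tier override) over the auto-assigned computable criteria --
#' curated wins per code -- and applies [acmg_combine()]. The
#' pathogenic/likely pathogenic ("PGV") set is the union of the top two
#' tiers.
#'
#' @param unique_variants output of [dedupe()] (or any data frame with
#'   `key`, `gene`, and representative record fields).
#' @param records the underlying annotation records (used to pick one
#'   representative record per key for auto-assignment); may be
#'   `unique_variants` itself if it carries the record fields.
#' @param curated optional curated evidence data frame (see
#'   [read_curated_evidence()]); entries for unknown keys warn and are
#'   ignored.
#' @param panel panel definition.
#' @return data frame: `key`, `gene`, `cdna`, `tier`, `fired_rule`,
#'   `conflict`, `criteria` (semicolon-joined effective codes), `provenance`
#'   ("auto", "curated", "auto+curated", or "tier_override").
#' @export
classify_cohort <- function(unique_variants, records = NULL, curated = NULL,
                            panel = default_panel()) {
  if (nrow(unique_variants) == 0)
    return(data.frame(key = character(), gene = character(),
                      cdna = character(), tier = character(),
                      fired_rule = character(), conflict = logical(),
                      criteria = character(), provenance = character(),
                      stringsAsFactors = FALSE))
  if (is.null(records)) records <- unique_variants
  if (!is.null(curated) && nrow(curated) > 0 && is.null(curated$key))
    curated$key <- variant_key(curated$gene, curated$cdna, panel)
  if (!is.null(curated)) {
    unknown <- setdiff(curated$key, unique_variants$key)
    if (length(unknown) > 0)
      warning(sprintf("curated evidence for unknown variant key(s) ignored: %s",
                      paste(unknown, collapse = ", ")))
  }
  rows <- lapply(seq_len(nrow(unique_variants)), function(i) {
    uv <- unique_variants[i, , drop = FALSE]
    rec <- records[match(uv$key, records$key), , drop = FALSE]
    gene_info <- panel[panel$symbol == uv$gene, , drop = FALSE]
    auto <- auto_assign(rec, gene_info)
    cur <- if (!is.null(curated)) curated[curated$key == uv$key, , drop = FALSE]
    provenance <- "auto"
    ev <- auto
    tier_override <- NA_character_
    if (!is.null(cur) && nrow(cur) > 0) {
      cur_codes <- unlist(strsplit(cur$criteria[1], ";", fixed = TRUE))
      cur_codes <- trimws(cur_codes[cur_codes != ""])
      if (length(cur_codes) > 0) {
        cur_ev <- evidence_set(cur_codes)
        keep <- !(auto$code %in% cur_ev$code)   # curated wins per code
        ev <- evidence_set(c(paste0(cur_ev$code, ":", cur_ev$strength),
                             paste0(auto$code[keep], ":",
                                    auto$strength[keep])))
        provenance <- "auto+curated"
      }
      if (!is.null(cur$tier) && !is.na(cur$tier[1]) && cur$tier[1] != "") {
        tier_override <- cur$tier[1]
        provenance <- "tier_override"
      }
    }
    cls <- acmg_combine(ev)
    if (!is.na(tier_override)) {
      cls$tier <- tier_override
      cls$fired_rule <- "curated tier override"
    }
    data.frame(key = uv$key, gene = uv$gene, cdna = uv$cdna, tier = cls$tier,
               fired_rule = cls$fired_rule, conflict = cls$conflict,
               criteria = paste(ev$code, collapse = ";"),
               provenance = provenance, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Select the pathogenic/likely pathogenic set from a classification
#'
#' @param classification output of [classify_cohort()].
#' @return the rows with tier in {pathogenic, likely_pathogenic}.
#' @export
pgv_set <- function(classification) {
  classification[classification$tier %in% c("pathogenic", "likely_pathogenic"),
                 , drop = FALSE]
}
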