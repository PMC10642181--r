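#' Default column dialect for annotation exports
#'
#' Maps the canonical record fields to the column headers of the annotation
#' export being read. The default mimics a per-sample panel export carrying,
#' per variant call: depth of coverage, minor allele frequency (MAF, gnomAD),
#' location, function, four pathogenicity prediction estimates (Sift,
#' Polyphen, Grantham, FATHMM) and the ClinVar significance. Exact header
#' names vary between annotation-software releases, hence configuration.
#'
#' @return named character vector: names are canonical field names, values
#'   the expected source column headers.
#' @export
default_dialect <- function() {
  c(sample_id = "Sample", gene = "Gene", transcript = "Transcript",
    cdna = "Coding", protein = "Protein", location = "Location",
    filter_status = "Filter", depth = "Coverage", maf = "MAF",
    clinvar = "ClinVar", sift = "Sift", polyphen = "Polyphen",
    grantham = "Grantham", fathmm = "FATHMM")
}

# fields a file must carry; predictions and protein may be absent
mandatory_fields <- function() {
  c("sample_id", "gene", "cdna", "location", "filter_status", "depth",
    "maf", "clinvar")
}

#' Normalize a ClinVar significance string to the package's categories
#'
#' Composite "Pathogenic/likely pathogenic" strings map to `path_or_lp` and
#' are treated as pathogenic-tier by the filters. Unrecognized non-empty
#' strings map to `no_entry` with a warning; blank/NA is `no_entry`.
#'
#' @param x character vector of ClinVar strings.
#' @return character vector over {pathogenic, likely_pathogenic, path_or_lp,
#'   uncertain, conflicting, benign, likely_benign, no_entry}.
#' @export
map_clinvar <- function(x) {
  canon <- c("pathogenic", "likely_pathogenic", "path_or_lp", "uncertain",
             "conflicting", "benign", "likely_benign", "no_entry")
  out <- character(length(x))
  lx <- tolower(trimws(as.character(x)))
  out[is.na(x) | lx %in% c("", "na", "no entry", "no_entry", ".")] <- "no_entry"
  pick <- function(pattern) out == "" & grepl(pattern, lx)
  out[pick("^pathogenic/likely[ _]pathogenic$|^path_or_lp$")] <- "path_or_lp"
  out[pick("^likely[ _]pathogenic$")] <- "likely_pathogenic"
  out[pick("^pathogenic$")] <- "pathogenic"
  out[pick("uncertain")] <- "uncertain"
  out[pick("conflicting")] <- "conflicting"
  out[pick("^likely[ _]benign$")] <- "likely_benign"
  out[pick("^benign$")] <- "benign"
  if (any(out == "")) {
    warning(sprintf("unrecognized ClinVar value(s) mapped to no_entry: %s",
                    paste(unique(x[out == ""]), collapse = "; ")))
    out[out == ""] <- "no_entry"
  }
  stopifnot(all(out %in% canon))
  out
}

# parse a vector of cDNA strings into a data frame of parsed fields
parse_cdna_fields <- function(cdna) {
  parsed <- lapply(cdna, parse_cdna)
  data.frame(
    cdna = vapply(parsed, `[[`, "", "cdna"),
    op = vapply(parsed, `[[`, "", "op"),
    cdna_position = vapply(parsed, `[[`, NA_integer_, "cdna_position"),
    cdna_end = vapply(parsed, `[[`, NA_integer_, "cdna_end"),
    intron_offset = vapply(parsed, `[[`, NA_integer_, "intron_offset"),
    stringsAsFactors = FALSE
  )
}

#' Build canonical annotation records from normalized columns
#'
#' Internal finishing step shared by all readers and the simulator: parses
#' the cDNA strings, flags splice candidates against the panel's exon
#' boundaries, classifies consequences, assigns variant keys and validates
#' field invariants.
#'
#' @param df data frame with at least the mandatory canonical columns.
#' @param panel panel definition.
#' @param splice_flank_bp window (coding bases) for exonic splice-candidate
#'   flagging (default 2).
#' @return annotation record data frame.
#' @export
as_annotation_records <- function(df, panel = default_panel(),
                                  splice_flank_bp = 2L) {
  for (f in setdiff(c("transcript", "protein", "sift", "polyphen", "grantham",
                      "fathmm"), names(df)))
    df[[f]] <- NA_character_
  df$sample_id <- as.character(df$sample_id)
  if (any(is.na(df$sample_id) | df$sample_id == ""))
    triage_error("sample_id must be non-empty", "validation_error")
  df$depth <- as.integer(df$depth)
  if (any(is.na(df$depth) | df$depth < 0))
    triage_error("depth must be a non-negative integer", "validation_error")
  df$maf <- suppressWarnings(as.numeric(df$maf))
  if (any(!is.na(df$maf) & (df$maf < 0 | df$maf > 1)))
    triage_error("maf must lie in [0,1] when present", "validation_error")
  df$clinvar <- map_clinvar(df$clinvar)
  if (!all(df$location %in% c("exonic", "flanking", "intronic", "utr",
                              "intergenic")))
    triage_error("location must be one of exonic/flanking/intronic/utr/intergenic",
                 "validation_error")
  df$filter_status <- ifelse(df$filter_status %in% "PASS", "PASS", "other")

  parsed <- lapply(df$cdna, parse_cdna)
  df$cdna <- vapply(parsed, `[[`, "", "cdna")
  df$cdna_position <- vapply(parsed, `[[`, NA_integer_, "cdna_position")
  df$cdna_end <- vapply(parsed, `[[`, NA_integer_, "cdna_end")
  df$intron_offset <- vapply(parsed, `[[`, NA_integer_, "intron_offset")
  df$splice_candidate <- vapply(seq_len(nrow(df)), function(i)
    is_splice_candidate(df$gene[i], parsed[[i]], panel, splice_flank_bp),
    logical(1))
  df$kind <- vapply(seq_len(nrow(df)), function(i)
    classify_consequence(parsed[[i]], df$protein[i], df$splice_candidate[i]),
    character(1))
  df$key <- variant_key(df$gene, df$cdna, panel)
  rownames(df) <- NULL
  df
}

#' Read per-sample annotation TSV files into one cohort record table
#'
#' Reads each file with the given column dialect and concatenates the records
#' in file order (the per-patient exports "merged into a single" table). A
#' missing MAF cell ("NA" or blank) stays missing, it is not coerced to 0.
#'
#' @param paths character vector of TSV file paths.
#' @param dialect column mapping, see [default_dialect()].
#' @param panel panel definition.
#' @return annotation record data frame.
#' @export
read_annotation_tsv <- function(paths, dialect = default_dialect(),
                                panel = default_panel()) {
  pieces <- lapply(paths, function(p) {
    raw <- read_tsv(p)
    need <- dialect[mandatory_fields()]
    missing <- setdiff(need, names(raw))
    if (length(missing) > 0)
      triage_error(sprintf("file %s lacks mandatory column(s): %s", p,
                           paste(missing, collapse = ", ")), "schema_error")
    present <- dialect[dialect %in% names(raw)]
    out <- raw[, unname(present), drop = FALSE]
    names(out) <- names(present)
    out
  })
  df <- do.call(rbind, pieces)
  as_annotation_records(df, panel)
}

#' Write annotation records as a TSV in a given dialect
#'
#' @param records annotation record data frame.
#' @param path output path.
#' @param dialect column mapping used for the header names.
#' @return `path`, invisibly.
#' @export
write_annotation_tsv <- function(records, path, dialect = default_dialect()) {
  out <- records[, names(dialect), drop = FALSE]
  names(out) <- unname(dialect)
  write_tsv(out, path)
}

# ---------------------------------------------------------------------------
# Patient registry
# ---------------------------------------------------------------------------

#' Read the patient registry
#'
#' One row per patient with demographics and clinical-pathological fields.
#' Enumerations are closed and validated; percentages are never stored
#' (always recomputed on demand).
#'
#' @param path TSV/CSV with columns `patient_id`, `age_dx`, `gender`,
#'   `localization`, `sidedness`, `ihc`, `family_history`, `deceased`.
#' @return validated registry data frame.
#' @export
read_registry <- function(path) {
  reg <- if (grepl("\\.csv$", path)) {
    utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  } else read_tsv(path)
  validate_registry(reg)
}

#' @rdname read_registry
#' @param reg registry data frame to validate in place.
#' @export
validate_registry <- function(reg) {
  reg$patient_id <- as.character(reg$patient_id)
  if (anyDuplicated(reg$patient_id))
    triage_error("duplicate patient_id in registry", "uniqueness_error")
  if (any(is.na(reg$age_dx) | reg$age_dx < 0 | reg$age_dx > 120))
    triage_error("age_dx must lie in [0,120]", "validation_error")
  if (!all(reg$gender %in% c("male", "female")))
    triage_error("gender must be male/female", "validation_error")
  if (!all(reg$localization %in% c("colon", "rectum", "both", "na")))
    triage_error("localization must be colon/rectum/both/na",
                 "validation_error")
  if (!all(reg$sidedness %in% c("right", "left", "both", "na")))
    triage_error("sidedness must be right/left/both/na", "validation_error")
  if (is.null(reg$ihc)) reg$ihc <- NA_character_
  if (is.null(reg$family_history)) reg$family_history <- NA
  if (is.null(reg$deceased)) reg$deceased <- NA
  reg$family_history <- as.logical(reg$family_history)
  reg$deceased <- as.logical(reg$deceased)
  reg
}

#' @rdname read_registry
#' @param path output path.
#' @export
write_registry <- function(reg, path) write_tsv(reg, path)

#' Bundle annotation records with the patient registry
#'
#' @param records annotation record data frame.
#' @param registry validated registry data frame.
#' @return list of class `cohort_table` with elements `records`, `registry`.
#' @export
cohort_table <- function(records, registry) {
  registry <- validate_registry(registry)
  orphan <- setdiff(unique(records$sample_id), registry$patient_id)
  if (length(orphan) > 0)
    triage_error(sprintf("sample_id(s) missing from registry: %s",
                         paste(orphan, collapse = ", ")), "validation_error")
  structure(list(records = records, registry = registry),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d annotation records, %d patients, %d genes\n",
              nrow(x$records), nrow(x$registry),
              length(unique(x$records$gene))))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Minimal VCF interchange (synthetic-data output format)
# ---------------------------------------------------------------------------

vcf_info_keys <- c("SID", "GENE", "TX", "HGVSC", "HGVSP", "LOC", "DP", "MAF",
                   "CLNSIG")

#' Write annotation records as a minimal VCF 4.2 file
#'
#' One VCF line per (variant, sample) record; the data model travels in INFO
#' keys (SID, GENE, TX, HGVSC, HGVSP, LOC, DP, MAF, CLNSIG). Coordinates are
#' transcript-space (CHROM is the transcript accession, POS the coding start
#' position), which is sufficient for lossless interchange of the fields the
#' model carries; genome projection is out of scope.
#'
#' @param records annotation record data frame.
#' @param path output `.vcf` path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(records, path) {
  enc <- function(x) gsub("[;= ]", "_", as.character(x))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=crctriage",
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"%s\">",
            vcf_info_keys, vcf_info_keys),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  info <- sprintf(
    "SID=%s;GENE=%s;TX=%s;HGVSC=%s;HGVSP=%s;LOC=%s;DP=%d;MAF=%s;CLNSIG=%s",
    enc(records$sample_id), records$gene,
    enc(ifelse(is.na(records$transcript), ".", records$transcript)),
    records$cdna,
    enc(ifelse(is.na(records$protein) | records$protein == "", ".",
               records$protein)),
    records$location, records$depth,
    ifelse(is.na(records$maf), ".", format(records$maf, scientific = FALSE,
                                           trim = TRUE)),
    records$clinvar)
  ref <- ifelse(is.na(records$cdna), "N",
                ifelse(grepl(">", records$cdna),
                       sub("^.*([ACGT])>[ACGT]$", "\\1", records$cdna), "N"))
  alt <- ifelse(grepl(">", records$cdna),
                sub("^.*[ACGT]>([ACGT])$", "\\1", records$cdna), "N")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t%s",
                  ifelse(is.na(records$transcript), records$gene,
                         records$transcript),
                  ifelse(is.na(records$cdna_position), 1L,
                         records$cdna_position),
                  ref, alt,
                  ifelse(records$filter_status == "PASS", "PASS", "."),
                  info)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a minimal VCF written by [write_vcf()]
#'
#' @param path `.vcf` path.
#' @param panel panel definition.
#' @return annotation record data frame; lossless round-trip against
#'   [write_vcf()] for the fields the data model carries.
#' @export
read_vcf <- function(path, panel = default_panel()) {
  lines <- readLines(path)
  if (length(lines) == 0 || !grepl("^##fileformat=VCF", lines[1]))
    triage_error(sprintf("malformed VCF header in %s", path), "format_error")
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0)
    return(as_annotation_records(
      data.frame(sample_id = character(), gene = character(),
                 cdna = character(), location = character(),
                 filter_status = character(), depth = integer(),
                 maf = numeric(), clinvar = character()), panel))
  fields <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(fields) < 8))
    triage_error("VCF body line with fewer than 8 columns", "format_error")
  info_get <- function(info, key) {
    m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]*)"), info))
    vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, "")
  }
  info <- vapply(fields, `[[`, "", 8L)
  filt <- vapply(fields, `[[`, "", 7L)
  dp <- info_get(info, "DP")
  if (any(is.na(dp)))
    triage_error(sprintf("VCF record(s) missing DP at line(s): %s",
                         paste(which(is.na(dp)), collapse = ", ")),
                 "format_error")
  maf <- info_get(info, "MAF")
  df <- data.frame(
    sample_id = info_get(info, "SID"),
    gene = info_get(info, "GENE"),
    transcript = ifelse(info_get(info, "TX") == ".", NA_character_,
                        info_get(info, "TX")),
    cdna = info_get(info, "HGVSC"),
    protein = ifelse(info_get(info, "HGVSP") == ".", NA_character_,
                     info_get(info, "HGVSP")),
    location = info_get(info, "LOC"),
    filter_status = ifelse(filt == "PASS", "PASS", "other"),
    depth = as.integer(dp),
    maf = suppressWarnings(as.numeric(ifelse(maf == ".", NA, maf))),
    clinvar = info_get(info, "CLNSIG"),
    stringsAsFactors = FALSE)
  as_annotation_records(df, panel)
}

# ---------------------------------------------------------------------------
# Packaged fixtures (verbatim table transcriptions)
# ---------------------------------------------------------------------------

#' Load a packaged cohort-table fixture
#'
#' Transcriptions of the published cohort tables shipped with the package:
#' `table2_aggregates` (demographics cross-tabs by mutation status),
#' `table3_pgv` (28 carrier rows of prioritised pathogenic/likely pathogenic
#' variants; one patient appears twice), `table4_ihc` (7 mutation-positive
#' patients with prior IHC results) and `table5_vus` (21 unique variants of
#' uncertain significance). Values are stored as printed, including known
#' internal typos, and normalised only on load (ClinVar category mapping).
#'
#' @param name one of "table2_aggregates", "table3_pgv", "table4_ihc",
#'   "table5_vus".
#' @return data frame.
#' @export
load_fixture <- function(name) {
  valid <- c("table2_aggregates", "table3_pgv", "table4_ihc", "table5_vus")
  if (!name %in% valid)
    triage_error(sprintf("unknown fixture '%s' (expected one of: %s)", name,
                         paste(valid, collapse = ", ")), "unknown_fixture")
  path <- system.file("extdata", paste0(name, ".tsv"), package = "crctriage")
  df <- read_tsv(path)
  if (name == "table3_pgv") {
    df$patient_id <- as.character(df$patient_id)
    df$clinvar <- map_clinvar(df$clinvar)
    df$acmg_tier <- c(Pathogenic = "pathogenic",
                      `Likely pathogenic` = "likely_pathogenic")[df$acmg_tier]
    df$novel <- startsWith(df$reported_before, "No")
    df$key <- variant_key(df$gene, df$cdna)
  }
  if (name == "table5_vus") {
    df$key <- variant_key(df$gene, df$cdna)
  }
  if (name == "table4_ihc") df$patient_id <- as.character(df$patient_id)
  df
}
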