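#' The default 14-gene hereditary colorectal cancer panel
#'
#' Returns the gene panel the pipeline screens: the four DNA mismatch repair
#' (MMR) genes whose defects cause Lynch syndrome, EPCAM, the polyposis genes,
#' the polymerase proofreading genes, and TP53. `risk_level` follows the
#' hereditary-CRC risk annotation of the panel design (POLD1/POLE are "risk"
#' genes via the proofreading-domain missense mechanism, TP53 is "lower" as a
#' syndrome gene where CRC is a rare manifestation, the rest are "high").
#' `lof_mechanism` marks genes where loss of function is an accepted disease
#' mechanism; it is `FALSE` for POLD1 and POLE, whose association runs through
#' proofreading-domain missense variants.
#'
#' `exon_boundaries` holds known coding coordinates of exon/intron junctions
#' used for splice-candidate detection of exonic variants. The shipped set is
#' deliberately partial (boundaries are configuration, not hard-coded
#' biology): it carries only junctions adjacent to variants the packaged
#' fixtures classify as splice-affecting.
#'
#' @return data frame with one row per gene: `symbol`, `refseq`, `locus`,
#'   `risk_level` (one of "high", "risk", "lower"), `phenotype`,
#'   `lof_mechanism` (logical), `exon_boundaries` (comma-separated coding
#'   coordinates, possibly empty).
#' @export
default_panel <- function() {
  path <- system.file("extdata", "panel_genes.tsv", package = "crctriage")
  read_panel(path)
}

#' Read a panel definition file
#'
#' @param path TSV with columns `symbol`, `refseq`, `locus`, `risk_level`,
#'   `phenotype`, `lof_mechanism`, and optional `exon_boundaries`
#'   (comma-separated 1-based coding coordinates of exon ends).
#' @return validated panel data frame (see [default_panel()]).
#' @export
read_panel <- function(path) {
  panel <- read_tsv(path)
  required <- c("symbol", "refseq", "locus", "risk_level", "phenotype",
                "lof_mechanism")
  missing <- setdiff(required, names(panel))
  if (length(missing) > 0)
    triage_error(sprintf("panel file %s lacks column(s): %s", path,
                         paste(missing, collapse = ", ")),
                 "schema_error")
  if (anyDuplicated(panel$symbol))
    triage_error("panel gene symbols must be unique", "validation_error")
  if (!all(grepl("^NM_\\d+\\.\\d+$", panel$refseq)))
    triage_error("panel refseq accessions must match the NM_ pattern",
                 "validation_error")
  if (!all(panel$risk_level %in% c("high", "risk", "lower")))
    triage_error("risk_level must be one of high/risk/lower",
                 "validation_error")
  panel$lof_mechanism <- as.logical(panel$lof_mechanism)
  if (is.null(panel$exon_boundaries)) panel$exon_boundaries <- ""
  panel$exon_boundaries[is.na(panel$exon_boundaries)] <- ""
  panel
}

mmr_genes <- function() c("MLH1", "MSH2", "MSH6", "PMS2")

# ---------------------------------------------------------------------------
# HGVS cDNA parsing (deliberately partial: substitutions, del, ins, delins,
# dup, and intronic +/- offsets -- the grammar subset the panel data use)
# ---------------------------------------------------------------------------

#' Parse a cDNA HGVS string
#'
#' Supports the subset of HGVS cDNA nomenclature occurring in panel output:
#' substitutions (`c.742C>T`), deletions (`c.2192_2196delTAACT`), insertions
#' (`c.187_188insG`), duplications, delins, and intronic offsets on either
#' coordinate (`c.117-1G>A`, `c.1476+2C>T`). Whitespace inside the string is
#' ignored (`c.1476 + 2C>T` parses as `c.1476+2C>T`). Strings beginning with
#' `c.` that do not match the supported grammar yield `kind = "unknown"` with
#' the raw string preserved so no record is silently dropped.
#'
#' @param hgvs a cDNA HGVS string beginning with `c.`.
#' @return a list of class `hgvs_variant`: `cdna` (normalized string),
#'   `op` ("sub", "del", "ins", "delins", "dup" or "unknown"), `cdna_position`
#'   (start coding coordinate), `cdna_end` (end coordinate, equal to start for
#'   single positions), `intron_offset` (signed integer or `NA`),
#'   `intron_offset_end`, `ref`/`alt` (for substitutions), `seq` (del/ins
#'   sequence if given), `span` (affected reference span in bases, `NA` when
#'   not applicable), `kind` (consequence class, refined by
#'   [classify_consequence()]).
#' @export
parse_cdna <- function(hgvs) {
  stopifnot(length(hgvs) == 1L)
  raw <- gsub("[[:space:]]", "", hgvs)
  if (!startsWith(raw, "c."))
    triage_error(sprintf("not a cDNA HGVS string (missing 'c.' prefix): '%s'",
                         hgvs), "format_error")
  body <- substring(raw, 3L)
  pos_re <- "(\\d+)([+-]\\d+)?"

  v <- list(cdna = raw, op = "unknown", cdna_position = NA_integer_,
            cdna_end = NA_integer_, intron_offset = NA_integer_,
            intron_offset_end = NA_integer_, ref = NA_character_,
            alt = NA_character_, seq = NA_character_, span = NA_integer_,
            kind = "unknown")
  class(v) <- "hgvs_variant"

  take_pos <- function(m, i) as.integer(m[i])
  take_off <- function(m, i) if (is.na(m[i]) || m[i] == "") NA_integer_ else as.integer(m[i])

  # substitution: c.117-1G>A
  m <- regmatches(body, regexec(paste0("^", pos_re, "([ACGT])>([ACGT])$"), body))[[1]]
  if (length(m) > 0) {
    v$op <- "sub"
    v$cdna_position <- v$cdna_end <- take_pos(m, 2)
    v$intron_offset <- v$intron_offset_end <- take_off(m, 3)
    v$ref <- m[4]; v$alt <- m[5]; v$span <- 1L
    v$kind <- default_kind(v)
    return(v)
  }

  # range or single-position del/dup/ins/delins: c.2192_2196delTAACT, c.717delA
  m <- regmatches(body, regexec(
    paste0("^", pos_re, "(?:_", pos_re, ")?(del|dup|ins|delins)([ACGT]*)$"),
    body))[[1]]
  if (length(m) > 0) {
    v$op <- m[6]
    v$cdna_position <- take_pos(m, 2)
    v$intron_offset <- take_off(m, 3)
    if (!is.na(m[4]) && m[4] != "") {
      v$cdna_end <- take_pos(m, 4)
      v$intron_offset_end <- take_off(m, 5)
    } else {
      v$cdna_end <- v$cdna_position
      v$intron_offset_end <- v$intron_offset
    }
    v$seq <- if (m[7] == "") NA_character_ else m[7]
    v$span <- switch(v$op,
      ins = 0L,  # insertion between flanking bases; no reference span removed
      v$cdna_end - v$cdna_position + 1L)
    v$kind <- default_kind(v)
    return(v)
  }

  v  # unparseable suffix: kind stays "unknown", raw string preserved
}

# consequence implied by the cDNA change alone (protein-free fallback)
default_kind <- function(v) {
  if (is_canonical_splice(v)) return("splice_site")
  if (!is.na(v$intron_offset)) return("intronic_other")
  "unknown"
}

is_canonical_splice <- function(v) {
  off <- c(v$intron_offset, v$intron_offset_end)
  any(!is.na(off) & abs(off) <= 2)
}

#' Reformat a parsed variant back to its HGVS string
#'
#' Inverse of [parse_cdna()]: `format_cdna(parse_cdna(x))` equals the
#' whitespace-normalized `x` for every supported string.
#'
#' @param v an `hgvs_variant`.
#' @return the cDNA HGVS string.
#' @export
format_cdna <- function(v) {
  stopifnot(inherits(v, "hgvs_variant"))
  if (v$op == "unknown") return(v$cdna)
  fmt_pos <- function(pos, off) {
    paste0(pos, if (!is.na(off)) sprintf("%+d", off) else "")
  }
  start <- fmt_pos(v$cdna_position, v$intron_offset)
  if (v$op == "sub") return(paste0("c.", start, v$ref, ">", v$alt))
  end <- fmt_pos(v$cdna_end, v$intron_offset_end)
  range <- if (v$cdna_end == v$cdna_position &&
               identical(v$intron_offset, v$intron_offset_end))
    start else paste0(start, "_", end)
  paste0("c.", range, v$op, if (!is.na(v$seq)) v$seq else "")
}

# ---------------------------------------------------------------------------
# Consequence classification
# ---------------------------------------------------------------------------

#' Classify the consequence of a variant from its protein annotation
#'
#' Combines the parsed cDNA change with the protein HGVS annotation to assign
#' a consequence class. Frameshift (`fs`) designations dominate, then
#' stop-gain (`Ter`), then synonymous (`p.X=`); a synonymous or unannotated
#' exonic change at/near an exon junction (canonical +/-1/2 intronic offset,
#' or `splice_candidate = TRUE`) is classified `splice_site`. Missense is
#' recognised from a `p.Aaa123Bbb` pattern; in-frame del/ins/dup (span
#' divisible by 3, no frameshift) is `inframe_indel`.
#'
#' @param v an `hgvs_variant` from [parse_cdna()].
#' @param protein protein HGVS string ("" or "p.?" when not available).
#' @param splice_candidate logical; `TRUE` when the exonic position lies
#'   within the configured flank of an annotated exon boundary (see
#'   [is_splice_candidate()]).
#' @return one of "missense", "nonsense", "frameshift", "inframe_indel",
#'   "splice_site", "synonymous", "intronic_other", "unknown".
#' @export
classify_consequence <- function(v, protein = "", splice_candidate = FALSE) {
  stopifnot(inherits(v, "hgvs_variant"))
  p <- gsub("[[:space:]]", "", protein %||% "")
  if (is.na(p)) p <- ""
  if (grepl("fs", p)) return("frameshift")
  if (is_canonical_splice(v)) return("splice_site")
  if (grepl("Ter$", p) && grepl("^p\\.", p)) return("nonsense")
  if (grepl("^p\\.[A-Za-z]{3}\\d+=$", p))
    return(if (isTRUE(splice_candidate)) "splice_site" else "synonymous")
  if (!is.na(v$intron_offset)) return("intronic_other")
  if (v$op %in% c("del", "ins", "dup", "delins")) {
    ins_len <- if (!is.na(v$seq)) nchar(v$seq) else 0L
    net <- switch(v$op, del = -v$span, ins = ins_len, dup = v$span,
                  delins = ins_len - v$span)
    if (!is.na(net) && net %% 3L == 0L) return("inframe_indel")
    return("frameshift")
  }
  if (grepl("^p\\.[A-Za-z]{3}\\d+[A-Za-z]{3}$", p)) return("missense")
  if (isTRUE(splice_candidate)) return("splice_site")
  "unknown"
}

#' Is an exonic position a splice candidate?
#'
#' `TRUE` when the variant's coding span comes within `flank_bp` bases of an
#' annotated exon boundary for its gene (boundaries supplied by the panel
#' definition; the paper-derived default panel ships a partial set).
#'
#' @param gene gene symbol.
#' @param v an `hgvs_variant`.
#' @param panel panel data frame with an `exon_boundaries` column.
#' @param flank_bp candidate window in coding bases (default 2).
#' @return logical.
#' @export
is_splice_candidate <- function(gene, v, panel = default_panel(), flank_bp = 2L) {
  row <- panel[panel$symbol == gene, , drop = FALSE]
  if (nrow(row) == 0 || is.na(row$exon_boundaries) || row$exon_boundaries == "")
    return(FALSE)
  b <- as.integer(strsplit(row$exon_boundaries, ",")[[1]])
  pos <- c(v$cdna_position, v$cdna_end)
  pos <- pos[!is.na(pos)]
  if (length(pos) == 0) return(FALSE)
  any(vapply(b, function(x) min(abs(pos - x)) <= flank_bp, logical(1)))
}

# ---------------------------------------------------------------------------
# Variant identity
# ---------------------------------------------------------------------------

#' Canonical variant key (gene + normalized cDNA)
#'
#' The sole basis of "unique variant" counting everywhere downstream:
#' two records are the same variant iff their gene symbols (case-insensitive)
#' and whitespace-stripped cDNA strings agree. Transcript version is ignored
#' deliberately: panel exports drift across annotation releases while the
#' coding change names the same allele.
#'
#' @param gene gene symbol, must be on the panel.
#' @param cdna cDNA HGVS string.
#' @param panel panel data frame (for the gene check).
#' @return character key, e.g. `"MSH2:c.187delG"`.
#' @export
variant_key <- function(gene, cdna, panel = default_panel()) {
  gene <- toupper(trimws(gene))
  bad <- !(gene %in% panel$symbol)
  if (any(bad))
    triage_error(sprintf("gene(s) not on the panel: %s",
                         paste(unique(gene[bad]), collapse = ", ")),
                 "unknown_gene_error")
  paste0(gene, ":", gsub("[[:space:]]", "", cdna))
}
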