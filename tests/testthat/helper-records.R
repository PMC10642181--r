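# Builders for small in-code fixtures used across test files.

# one canonical annotation row with overridable fields
toy_record <- function(sample_id = "S1", gene = "MSH2", cdna = "c.100A>G",
                       protein = "p.Lys34Glu", location = "exonic",
                       filter_status = "PASS", depth = 500L, maf = NA_real_,
                       clinvar = "no_entry", sift = NA_character_,
                       polyphen = NA_character_, grantham = NA_character_,
                       fathmm = NA_character_) {
  data.frame(sample_id = sample_id, gene = gene, transcript = NA_character_,
             cdna = cdna, protein = protein, location = location,
             filter_status = filter_status, depth = depth, maf = maf,
             clinvar = clinvar, sift = sift, polyphen = polyphen,
             grantham = grantham, fathmm = fathmm, stringsAsFactors = FALSE)
}

toy_records <- function(...) {
  as_annotation_records(do.call(rbind, list(...)))
}

# random annotation records exercising every filter dimension (for
# property-style funnel tests); deterministic given the RNG state
random_records <- function(n) {
  genes <- c("MLH1", "MSH2", "MSH6", "PMS2", "APC", "TP53")
  pos <- sample(5000:9000, n)
  syn <- runif(n) < 0.25
  intronic <- runif(n) < 0.25
  cdna <- ifelse(intronic,
                 sprintf("c.%d+%dA>G", pos, sample(c(1:3, 10:60), n, TRUE)),
                 sprintf("c.%dA>G", pos))
  protein <- ifelse(intronic, "p.?",
                    ifelse(syn, sprintf("p.Ala%d=", pos %/% 3),
                           sprintf("p.Ala%dVal", pos %/% 3)))
  df <- data.frame(
    sample_id = sample(sprintf("S%02d", 1:8), n, TRUE),
    gene = sample(genes, n, TRUE), transcript = NA_character_,
    cdna = cdna, protein = protein,
    location = ifelse(intronic, "intronic",
                      sample(c("exonic", "utr"), n, TRUE, prob = c(0.9, 0.1))),
    filter_status = sample(c("PASS", "other"), n, TRUE, prob = c(0.8, 0.2)),
    depth = sample(c(5:40, 200:700), n, TRUE),
    maf = ifelse(runif(n) < 0.4, NA_real_, runif(n, 0, 0.4)),
    clinvar = sample(c("no_entry", "benign", "likely_benign", "uncertain",
                       "pathogenic", "conflicting"), n, TRUE),
    sift = NA_character_, polyphen = NA_character_,
    grantham = NA_character_, fathmm = NA_character_,
    stringsAsFactors = FALSE)
  as_annotation_records(df)
}

# independent one-pass re-statement of the funnel predicate (excludes the
# cohort-dependent artifact flag, tested separately)
single_pass_oracle <- function(records, cfg = filter_config()) {
  keep <- records$filter_status == "PASS"
  syn <- records$kind == "synonymous"
  rescued <- cfg$synonymous_rescue &
    (records$clinvar %in% c("pathogenic", "likely_pathogenic", "path_or_lp") |
       records$splice_candidate)
  keep <- keep & (!syn | rescued)
  flank <- records$location == "flanking" |
    (records$location == "intronic" & !is.na(records$intron_offset) &
       abs(records$intron_offset) <= cfg$flank_bp)
  keep <- keep & (records$location == "exonic" | flank)
  keep <- keep & (is.na(records$maf) | records$maf < cfg$maf_max)
  keep <- keep & records$clinvar %in% cfg$clinvar_keep
  keep <- keep & records$depth > cfg$depth_min
  records[keep, , drop = FALSE]
}
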