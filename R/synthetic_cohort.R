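#' Simulation configuration for synthetic annotated cohorts
#'
#' Describes a cohort in the shape the pipeline consumes: per-patient
#' annotated variant loads (default 100-200 calls per individual, the band
#' seen in real panel exports), planted pathogenic/likely pathogenic variants
#' and VUSs with known carriers, pseudogene-shadow variants (annotated
#' identically to real calls and distinguishable only through the homology
#' flag and a verification ledger), recurrent-indel artifacts, and a benign
#' background model: a common clump (MAF ~ Uniform(0.05, 0.5), ClinVar
#' benign) and rare noise (MAF ~ Uniform(0, 0.05) or unknown, no ClinVar
#' entry). Depth is negative-binomial around a mean of 604x, the panel's
#' reported mean coverage. Registry ages are a discretised truncated normal
#' (mean 36, sd 9, bounds 18-58; median ~37), gender is balanced, and tumour
#' localisation is colon:rectum roughly 3:1.
#'
#' @param n_patients cohort size (default 100).
#' @param variants_per_patient integer range, calls per individual.
#' @param planted_pgvs `NULL` or data frame `gene`, `cdna`, `protein`,
#'   `tier`, `carriers` (comma-separated patient ids), optional
#'   `reported_before`.
#' @param planted_vus `NULL` or data frame `gene`, `cdna`, `protein`,
#'   `carriers`.
#' @param shadow_variants `NULL` or data frame `gene`, `cdna`, `protein`,
#'   `carriers` (cDNA spans must lie in a homology region to behave as
#'   shadows).
#' @param artifact_indels `NULL` or data frame `gene`, `cdna`,
#'   `sample_fraction`.
#' @param depth_mean,depth_size negative-binomial depth model (mu, size).
#' @param age_mean,age_sd,age_range registry age model.
#' @param seed integer seed; all randomness flows from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 100L,
                       variants_per_patient = c(100L, 200L),
                       planted_pgvs = NULL, planted_vus = NULL,
                       shadow_variants = NULL, artifact_indels = NULL,
                       depth_mean = 604, depth_size = 8,
                       age_mean = 36, age_sd = 9, age_range = c(18L, 58L),
                       seed = 1L) {
  stopifnot(n_patients >= 1, length(variants_per_patient) == 2,
            variants_per_patient[1] <= variants_per_patient[2])
  structure(list(n_patients = as.integer(n_patients),
                 variants_per_patient = as.integer(variants_per_patient),
                 planted_pgvs = planted_pgvs, planted_vus = planted_vus,
                 shadow_variants = shadow_variants,
                 artifact_indels = artifact_indels,
                 depth_mean = depth_mean, depth_size = depth_size,
                 age_mean = age_mean, age_sd = age_sd,
                 age_range = as.integer(age_range), seed = as.integer(seed)),
            class = "sim_config")
}

sim_patient_ids <- function(n) sprintf("P%03d", seq_len(n))

#' Generate a synthetic patient registry
#'
#' Ages are drawn from a normal distribution discretised to whole years and
#' truncated by rejection to the configured bounds; gender is balanced;
#' localisation is colon:rectum 3:1; sidedness is right:left 1:1. Uses the
#' current RNG state ([generate_cohort()] seeds it from the config).
#'
#' @param cfg a [sim_config()].
#' @return registry data frame (see [read_registry()]).
#' @export
generate_registry <- function(cfg) {
  n <- cfg$n_patients
  draw_age <- function(m) {
    a <- round(stats::rnorm(m, cfg$age_mean, cfg$age_sd))
    a[a >= cfg$age_range[1] & a <= cfg$age_range[2]]
  }
  ages <- integer(0)
  while (length(ages) < n) ages <- c(ages, draw_age(2L * n))
  data.frame(
    patient_id = sim_patient_ids(n),
    age_dx = ages[seq_len(n)],
    gender = sample(c("male", "female"), n, replace = TRUE),
    localization = sample(c("colon", "rectum"), n, replace = TRUE,
                          prob = c(3, 1)),
    sidedness = sample(c("right", "left"), n, replace = TRUE),
    ihc = NA_character_, family_history = NA, deceased = NA,
    stringsAsFactors = FALSE)
}

# background fate labels -> the funnel stage designed to remove the record
background_fates <- c(fail_pass = "pass", synonymous = "functional",
                      deep_intronic = "functional", common = "maf",
                      benign = "clinvar", low_depth = "depth",
                      rare_noise = "prioritized")

#' Generate a synthetic annotated cohort with a ground-truth table
#'
#' Truth-table-driven construction: every background record is built to fail
#' exactly one chosen funnel stage (caller status, synonymous function, deep
#' intronic location, common allele frequency, benign ClinVar entry, or low
#' depth), or to survive as rare classifiable noise; planted variants are
#' built to survive every stage. Funnel-stage counts are therefore exactly
#' checkable against the truth table, not just statistically. Deterministic
#' for a fixed seed.
#'
#' @param cfg a [sim_config()].
#' @return list of class `sim_cohort`: `records` (annotation records),
#'   `registry`, `truth` (per unique planted/background variant: `key`,
#'   `class`, `expected_fate`, `expected_tier`, `expected_verification`),
#'   `curated` (curated-evidence rows for the planted PGVs and shadows),
#'   `patient_truth` (per patient: expected PGV positivity before and after
#'   verification).
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  registry <- generate_registry(cfg)
  ids <- registry$patient_id
  panel <- default_panel()

  check_carriers <- function(planted, what) {
    if (is.null(planted)) return(invisible())
    carriers <- unlist(strsplit(planted$carriers, ",", fixed = TRUE))
    bad <- setdiff(trimws(carriers), ids)
    if (length(bad) > 0)
      triage_error(sprintf("%s carrier id(s) outside the registry: %s", what,
                           paste(bad, collapse = ", ")), "config_error")
  }
  check_carriers(cfg$planted_pgvs, "planted PGV")
  check_carriers(cfg$planted_vus, "planted VUS")
  check_carriers(cfg$shadow_variants, "shadow variant")

  depth_hi <- function(m)
    pmax(31L, as.integer(stats::rnbinom(m, mu = cfg$depth_mean,
                                        size = cfg$depth_size)))

  rec <- function(sample_id, gene, cdna, protein, location, filter_status,
                  depth, maf, clinvar) {
    data.frame(sample_id = sample_id, gene = gene, transcript = NA_character_,
               cdna = cdna, protein = protein, location = location,
               filter_status = filter_status, depth = depth, maf = maf,
               clinvar = clinvar, sift = NA_character_,
               polyphen = NA_character_, grantham = NA_character_,
               fathmm = NA_character_, stringsAsFactors = FALSE)
  }

  pieces <- list()
  truth <- list()

  expand_planted <- function(planted) {
    lapply(seq_len(nrow(planted)), function(i)
      trimws(strsplit(planted$carriers[i], ",", fixed = TRUE)[[1]]))
  }

  # --- planted PGVs: survive every stage, curated tier evidence ------------
  curated <- data.frame(gene = character(), cdna = character(),
                        criteria = character(), tier = character(),
                        stringsAsFactors = FALSE)
  if (!is.null(cfg$planted_pgvs) && nrow(cfg$planted_pgvs) > 0) {
    p <- cfg$planted_pgvs
    carr <- expand_planted(p)
    idx <- rep(seq_len(nrow(p)), lengths(carr))
    pieces$pgv <- rec(unlist(carr), p$gene[idx], p$cdna[idx], p$protein[idx],
                      "exonic", "PASS", depth_hi(length(idx)), NA_real_,
                      "pathogenic")
    curated <- rbind(curated,
                     data.frame(gene = p$gene, cdna = p$cdna, criteria = "",
                                tier = p$tier, stringsAsFactors = FALSE))
    truth$pgv <- data.frame(gene = p$gene, cdna = p$cdna, class = "pgv",
                            expected_fate = "prioritized",
                            expected_tier = p$tier,
                            expected_verification = "verified",
                            stringsAsFactors = FALSE)
  }

  # --- planted VUSs: ClinVar uncertain, survive the VUS funnel -------------
  if (!is.null(cfg$planted_vus) && nrow(cfg$planted_vus) > 0) {
    p <- cfg$planted_vus
    carr <- expand_planted(p)
    idx <- rep(seq_len(nrow(p)), lengths(carr))
    pieces$vus <- rec(unlist(carr), p$gene[idx], p$cdna[idx], p$protein[idx],
                      "exonic", "PASS", depth_hi(length(idx)), NA_real_,
                      "uncertain")
    truth$vus <- data.frame(gene = p$gene, cdna = p$cdna, class = "vus",
                            expected_fate = "prioritized",
                            expected_tier = "vus",
                            expected_verification = NA_character_,
                            stringsAsFactors = FALSE)
  }

  # --- shadow variants: look exactly like planted PGVs ---------------------
  if (!is.null(cfg$shadow_variants) && nrow(cfg$shadow_variants) > 0) {
    p <- cfg$shadow_variants
    carr <- expand_planted(p)
    idx <- rep(seq_len(nrow(p)), lengths(carr))
    pieces$shadow <- rec(unlist(carr), p$gene[idx], p$cdna[idx],
                         p$protein[idx], "exonic", "PASS",
                         depth_hi(length(idx)), NA_real_, "pathogenic")
    curated <- rbind(curated,
                     data.frame(gene = p$gene, cdna = p$cdna, criteria = "",
                                tier = "pathogenic", stringsAsFactors = FALSE))
    truth$shadow <- data.frame(gene = p$gene, cdna = p$cdna, class = "shadow",
                               expected_fate = "prioritized",
                               expected_tier = "pathogenic",
                               expected_verification = "pseudogene",
                               stringsAsFactors = FALSE)
  }

  # --- recurrent indel artifacts -------------------------------------------
  if (!is.null(cfg$artifact_indels) && nrow(cfg$artifact_indels) > 0) {
    p <- cfg$artifact_indels
    carr <- lapply(seq_len(nrow(p)), function(i)
      sample(ids, max(1L, ceiling(p$sample_fraction[i] * length(ids)))))
    idx <- rep(seq_len(nrow(p)), lengths(carr))
    pieces$artifact <- rec(unlist(carr), p$gene[idx], p$cdna[idx],
                           NA_character_, "exonic", "PASS",
                           depth_hi(length(idx)), NA_real_, "no_entry")
    truth$artifact <- data.frame(gene = p$gene, cdna = p$cdna,
                                 class = "artifact",
                                 expected_fate = "artifact",
                                 expected_tier = NA_character_,
                                 expected_verification = NA_character_,
                                 stringsAsFactors = FALSE)
  }

  # --- background: each record built to fail one chosen stage --------------
  n_bg_per <- sample(cfg$variants_per_patient[1]:cfg$variants_per_patient[2],
                     cfg$n_patients, replace = TRUE)
  n_bg <- sum(n_bg_per)
  if (n_bg > 0) {
    fate <- sample(names(background_fates), n_bg, replace = TRUE,
                   prob = c(0.05, 0.25, 0.20, 0.25, 0.15, 0.05, 0.05))
    gene <- sample(panel$symbol, n_bg, replace = TRUE)
    # unique positions per record keep background keys distinct from planted
    pos <- 10000L + seq_len(n_bg)
    base_from <- c("A", "C", "G", "T")[1L + (pos %% 4L)]
    base_to <- c("C", "G", "T", "A")[1L + (pos %% 4L)]
    cdna <- sprintf("c.%d%s>%s", pos, base_from, base_to)
    protein <- sprintf("p.Ala%dVal", pos %/% 3L)
    location <- rep("exonic", n_bg)
    filter_status <- rep("PASS", n_bg)
    depth <- depth_hi(n_bg)
    maf <- rep(NA_real_, n_bg)
    clinvar <- rep("no_entry", n_bg)

    filter_status[fate == "fail_pass"] <- "other"
    protein[fate == "synonymous"] <-
      sprintf("p.Ala%d=", pos[fate == "synonymous"] %/% 3L)
    deep <- fate == "deep_intronic"
    location[deep] <- "intronic"
    cdna[deep] <- sprintf("c.%d+%d%s>%s", pos[deep], 40L + (pos[deep] %% 200L),
                          base_from[deep], base_to[deep])
    protein[deep] <- "p.?"
    common <- fate == "common"
    maf[common] <- stats::runif(sum(common), 0.05, 0.5)
    clinvar[common] <- "benign"
    ben <- fate == "benign"
    maf[ben] <- stats::runif(sum(ben), 0, 0.049)
    clinvar[ben] <- sample(c("benign", "likely_benign"), sum(ben),
                           replace = TRUE)
    low <- fate == "low_depth"
    depth[low] <- sample(1:30, sum(low), replace = TRUE)
    rare <- fate == "rare_noise"
    maf[rare] <- stats::runif(sum(rare), 0, 0.0009)

    pieces$background <- rec(rep(ids, n_bg_per), gene, cdna, protein,
                             location, filter_status, depth, maf, clinvar)
    truth$background <- data.frame(gene = gene, cdna = cdna,
                                   class = "background",
                                   expected_fate = unname(background_fates[fate]),
                                   expected_tier =
                                     ifelse(fate == "rare_noise", "vus",
                                            NA_character_),
                                   expected_verification = NA_character_,
                                   stringsAsFactors = FALSE)
  }

  records <- as_annotation_records(do.call(rbind, unname(pieces)), panel)
  truth <- do.call(rbind, unname(truth))
  truth$key <- variant_key(truth$gene, truth$cdna, panel)
  if (anyDuplicated(truth$key[truth$class != "background"]))
    triage_error("planted variant keys must be unique", "config_error")

  pgv_carriers <- if (!is.null(cfg$planted_pgvs) && nrow(cfg$planted_pgvs) > 0)
    unique(trimws(unlist(strsplit(cfg$planted_pgvs$carriers, ",")))) else
      character()
  shadow_carriers <- if (!is.null(cfg$shadow_variants) &&
                         nrow(cfg$shadow_variants) > 0)
    unique(trimws(unlist(strsplit(cfg$shadow_variants$carriers, ",")))) else
      character()
  patient_truth <- data.frame(
    patient_id = ids,
    expected_positive_pre = ids %in% union(pgv_carriers, shadow_carriers),
    expected_positive_post = ids %in% pgv_carriers,
    stringsAsFactors = FALSE)

  structure(list(records = records, registry = registry, truth = truth,
                 curated = curated, patient_truth = patient_truth,
                 config = cfg),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("<sim_cohort> %d patients, %d records (%s)\n",
              nrow(x$registry), nrow(x$records),
              paste(sprintf("%s: %d", names(table(x$truth$class)),
                            table(x$truth$class)), collapse = ", ")))
  invisible(x)
}

#' Write a simulated cohort's files
#'
#' Emits the interchange set: annotation TSV, minimal VCF, registry TSV and
#' truth-table TSV.
#'
#' @param sim a `sim_cohort`.
#' @param dir output directory (created if absent).
#' @return named character vector of paths, invisibly.
#' @export
write_sim_cohort <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(annotation = file.path(dir, "annotation.tsv"),
             vcf = file.path(dir, "cohort.vcf"),
             registry = file.path(dir, "registry.tsv"),
             truth = file.path(dir, "truth.tsv"),
             curated = file.path(dir, "curated_evidence.tsv"))
  write_annotation_tsv(sim$records, paths["annotation"])
  write_vcf(sim$records, paths["vcf"])
  write_registry(sim$registry, paths["registry"])
  write_tsv(sim$truth, paths["truth"])
  write_tsv(sim$curated, paths["curated"])
  invisible(paths)
}
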