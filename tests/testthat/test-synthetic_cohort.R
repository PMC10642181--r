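small_cfg <- function(seed, ...) {
  sim_config(n_patients = 20L, variants_per_patient = c(15L, 30L),
             seed = seed, ...)
}

pgv_plan <- function(carriers) {
  data.frame(gene = c("MLH1", "MSH2", "TP53"),
             cdna = c("c.350G>A", "c.1861C>T", "c.818G>A"),
             protein = c("p.Trp117Ter", "p.Arg621Ter", "p.Arg273His"),
             tier = c("pathogenic", "pathogenic", "likely_pathogenic"),
             carriers = carriers, stringsAsFactors = FALSE)
}

test_that("generation is deterministic for a fixed seed", {
  cfg <- small_cfg(101, planted_pgvs = pgv_plan(c("P001", "P002,P003", "P004")))
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$registry, b$registry)
  expect_identical(a$truth, b$truth)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  pa <- write_sim_cohort(a, d1); pb <- write_sim_cohort(b, d2)
  for (nm in names(pa))
    expect_identical(readLines(pa[[nm]]), readLines(pb[[nm]]), label = nm)
})

test_that("planted carriers must exist in the registry", {
  cfg <- small_cfg(5, planted_pgvs = pgv_plan(c("P001", "P099", "P002")))
  expect_error(generate_cohort(cfg), class = "config_error")
})

test_that("background-only cohorts yield zero PGV carriers", {
  sim <- generate_cohort(small_cfg(7))
  run <- run_triage(sim$records, sim$registry, curated = NULL, ledger = NULL)
  expect_equal(run$summary$pre_verification$carriers, 0)
  expect_equal(nrow(pgv_set(run$classified)), 0)
})

test_that("each background record fails exactly its designed stage", {
  sim <- generate_cohort(small_cfg(13))
  cfg <- filter_config()
  out <- run_pgv_funnel(sim$records, cfg)
  truth <- sim$truth
  # survivors are exactly the records designed to be prioritized
  expect_setequal(out$records$key,
                  truth$key[truth$expected_fate == "prioritized"])
  # per-stage removals match the truth table exactly
  fate_counts <- table(truth$expected_fate)
  stage_drop <- -diff(out$stages$n_records)
  names(stage_drop) <- out$stages$stage[-1]
  for (st in c("pass", "functional", "maf", "clinvar", "depth"))
    expect_equal(unname(stage_drop[st]),
                 sum(truth$expected_fate == st), label = st)
})

test_that("planted variants are recovered exactly across 20 seeded cohorts", {
  for (seed in 1:20) {
    set.seed(seed * 1000)
    ids <- sprintf("P%03d", sample(20, 6))
    carriers <- c(paste(ids[1:2], collapse = ","), ids[3],
                  paste(ids[4:5], collapse = ","))
    cfg <- small_cfg(seed, planted_pgvs = pgv_plan(carriers))
    sim <- generate_cohort(cfg)
    run <- run_triage(sim$records, sim$registry, curated = sim$curated,
                      ledger = NULL)
    found <- sort(unique(run$verified$verified$sample_id))
    planted <- sort(unique(ids[1:5]))
    expect_identical(found, planted)   # sensitivity and specificity both 1
    res <- run$resolution
    expect_setequal(res$patient_id[res$status == "resolved"], planted)
  }
})

test_that("pseudogene shadow variants never reach verified yields", {
  for (seed in c(3, 17, 29)) {
    cfg <- small_cfg(seed,
                     planted_pgvs = pgv_plan(c("P001", "P002", "P003")),
                     shadow_variants = data.frame(
                       gene = "PMS2", cdna = "c.2192_2196delTAACT",
                       protein = "p.Leu731CysfsTer3",
                       carriers = "P004,P005", stringsAsFactors = FALSE))
    sim <- generate_cohort(cfg)
    run <- run_triage(sim$records, sim$registry, curated = sim$curated,
                      ledger = NULL)
    # shadows are found pre-verification (indistinguishable by annotation)
    expect_true("P004" %in% run$pgv_calls$sample_id)
    # but never verified without a confirmed_present ledger entry
    expect_false(any(c("P004", "P005") %in% run$verified$verified$sample_id))
    expect_true(all(run$verified$unverified$gene == "PMS2"))
    expect_setequal(unique(run$verified$unverified$sample_id),
                    c("P004", "P005"))
  }
})

test_that("planted artifacts are flagged and never classified", {
  cfg <- small_cfg(23, artifact_indels = data.frame(
    gene = "APC", cdna = "c.4444delA", sample_fraction = 0.4,
    stringsAsFactors = FALSE))
  sim <- generate_cohort(cfg)
  out <- run_pgv_funnel(sim$records, filter_config())
  expect_true(all(out$artifacts$key == "APC:c.4444delA"))
  expect_gt(nrow(out$artifacts), 0)
  expect_false("APC:c.4444delA" %in% out$unique_variants$key)
  cls <- classify_cohort(out$unique_variants, records = out$records)
  expect_false("APC:c.4444delA" %in% cls$key)
})

test_that("registry model respects its bounds and target median", {
  sim <- generate_cohort(small_cfg(47))
  reg <- sim$registry
  expect_true(all(reg$age_dx >= 18 & reg$age_dx <= 58))
  expect_true(all(reg$gender %in% c("male", "female")))

  set.seed(99)
  big <- generate_registry(sim_config(n_patients = 10000L, seed = 99))
  expect_true(all(big$age_dx >= 18 & big$age_dx <= 58))
  expect_lt(abs(stats::median(big$age_dx) - 37), 2)
  # localisation roughly colon:rectum 3:1
  expect_gt(mean(big$localization == "colon"), 0.7)

  one <- generate_registry(sim_config(n_patients = 1L))
  expect_equal(nrow(one), 1)
})

test_that("per-patient variant loads stay in the configured band", {
  sim <- generate_cohort(sim_config(n_patients = 10L, seed = 3))
  loads <- table(sim$records$sample_id)
  expect_true(all(loads >= 100 & loads <= 200))
})
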