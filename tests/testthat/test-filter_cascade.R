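cfg <- filter_config()

test_that("individual stages implement the published cut-offs", {
  recs <- toy_records(
    toy_record("S1", cdna = "c.101A>G", filter_status = "PASS"),
    toy_record("S2", cdna = "c.102A>G", filter_status = "other"))
  expect_equal(stage_pass(recs)$sample_id, "S1")
  expect_equal(nrow(stage_pass(recs[2, ])), 0)

  # MAF: strict upper bound, missing retained as "rare, unknown"
  recs <- toy_records(
    toy_record("S1", cdna = "c.103A>G", maf = 0.002),
    toy_record("S2", cdna = "c.104A>G", maf = NA_real_),
    toy_record("S3", cdna = "c.105A>G", maf = 0.05),
    toy_record("S4", cdna = "c.106A>G", maf = 0.0499))
  expect_equal(stage_maf(recs, cfg)$sample_id, c("S1", "S2", "S4"))

  # depth: "30x or less" excluded
  recs <- toy_records(
    toy_record("S1", cdna = "c.107A>G", depth = 31L),
    toy_record("S2", cdna = "c.108A>G", depth = 30L),
    toy_record("S3", cdna = "c.109A>G", depth = 604L))
  expect_equal(stage_depth(recs, cfg)$sample_id, c("S1", "S3"))

  # ClinVar: benign tiers out, blank/uncertain/conflicting retained
  recs <- toy_records(
    toy_record("S1", cdna = "c.110A>G", clinvar = "benign"),
    toy_record("S2", cdna = "c.111A>G", clinvar = "no_entry"),
    toy_record("S3", cdna = "c.112A>G", clinvar = "conflicting"),
    toy_record("S4", cdna = "c.113A>G", clinvar = "likely_benign"))
  expect_equal(stage_clinvar(recs, cfg)$sample_id, c("S2", "S3"))
})

test_that("functional stage removes synonymous unless rescued, keeps flanking", {
  recs <- toy_records(
    toy_record("S1", gene = "MLH1", cdna = "c.1731G>A", protein = "p.Ser577=",
               clinvar = "pathogenic"),   # splice candidate at exon boundary
    toy_record("S2", cdna = "c.300G>A", protein = "p.Thr100=",
               clinvar = "pathogenic"),   # synonymous, rescued by ClinVar
    toy_record("S2b", cdna = "c.303G>A", protein = "p.Thr101="),  # dropped
    toy_record("S3", gene = "MLH1", cdna = "c.117-1G>A", protein = "p.?",
               location = "intronic", clinvar = "pathogenic"), # flanking
    toy_record("S4", cdna = "c.500+45A>G", protein = "p.?",
               location = "intronic"),                        # too deep
    toy_record("S5", cdna = "c.600A>G", location = "utr"))
  out <- stage_functional(recs, cfg)
  expect_equal(out$sample_id, c("S1", "S2", "S3"))
  # with rescue off, the pathogenic synonymous call is lost again, while
  # the boundary call survives on its splice classification
  no_rescue <- filter_config(synonymous_rescue = FALSE)
  expect_equal(stage_functional(recs, no_rescue)$sample_id, c("S1", "S3"))
})

test_that("artifact flag hits recurrent indels only", {
  mk <- function(ids, cdna, protein) do.call(rbind, lapply(ids, function(s)
    toy_record(s, cdna = cdna, protein = protein)))
  recs <- as_annotation_records(rbind(
    mk(sprintf("S%03d", 1:30), "c.400delA", NA_character_),   # 30% of 100
    mk(sprintf("S%03d", 1:30), "c.500A>G", "p.Lys167Glu"),
    mk(sprintf("S%03d", 1:10), "c.600delT", NA_character_)))  # 10% of 100
  out <- flag_artifacts(recs, n_samples = 100, cfg = cfg)
  expect_true(all(out$artifact[out$cdna == "c.400delA"]))
  expect_false(any(out$artifact[out$cdna == "c.500A>G"]))   # substitutions never
  expect_false(any(out$artifact[out$cdna == "c.600delT"]))  # below threshold
})

test_that("dedupe collapses carrier rows to unique variants", {
  t3 <- load_fixture("table3_pgv")
  recs <- as_annotation_records(data.frame(
    sample_id = t3$patient_id, gene = t3$gene, cdna = t3$cdna,
    protein = t3$protein, location = "exonic", filter_status = "PASS",
    depth = 604L, maf = t3$maf, clinvar = t3$clinvar,
    stringsAsFactors = FALSE))
  uv <- dedupe(recs)
  expect_equal(nrow(uv), 24)
  expect_equal(sum(uv$n_carriers), 28)
  expect_equal(uv$n_carriers[uv$key == "PMS2:c.2192_2196delTAACT"], 3)
  expect_equal(uv$carriers[uv$key == "MLH1:c.117-1G>A"], "1,3")
  expect_equal(nrow(dedupe(recs[0, ])), 0)
})

test_that("staged funnel equals the single-pass predicate oracle", {
  set.seed(42)
  for (rep in 1:25) {
    recs <- random_records(sample(40:120, 1))
    rep_out <- run_pgv_funnel(recs, cfg, n_samples = 50)
    oracle <- single_pass_oracle(recs, cfg)
    # no artifacts possible here (all substitutions unique per record)
    expect_setequal(rownames(rep_out$records), rownames(oracle))
  }
})

test_that("funnel counts are monotone and the funnel is idempotent", {
  set.seed(7)
  for (rep in 1:1000) {
    recs <- random_records(30)
    out <- run_pgv_funnel(recs, cfg, n_samples = 8)
    expect_true(all(diff(out$stages$n_records) <= 0))
    expect_true(all(diff(out$stages$n_unique) <= 0))
    again <- run_pgv_funnel(out$records, cfg, n_samples = 8)
    expect_equal(again$records, out$records)
  }
})

test_that("funnel output is invariant to record order", {
  set.seed(11)
  recs <- random_records(150)
  a <- run_pgv_funnel(recs, cfg, n_samples = 8)
  b <- run_pgv_funnel(recs[sample(nrow(recs)), ], cfg, n_samples = 8)
  expect_setequal(a$unique_variants$key, b$unique_variants$key)
  expect_equal(a$stages$n_records, b$stages$n_records)
  ca <- a$unique_variants$carriers[order(a$unique_variants$key)]
  cb <- b$unique_variants$carriers[order(b$unique_variants$key)]
  expect_equal(ca, cb)
})

test_that("a permissive config reduces the funnel to deduplication", {
  open_cfg <- filter_config(maf_max = 1, depth_min = 0,
                            clinvar_keep = c("pathogenic", "likely_pathogenic",
                                             "path_or_lp", "uncertain",
                                             "conflicting", "no_entry",
                                             "benign", "likely_benign"))
  recs <- toy_records(
    toy_record("S1", cdna = "c.700C>T", protein = "p.Arg234Trp", maf = 0.3,
               depth = 5L, clinvar = "benign"),
    toy_record("S2", cdna = "c.700C>T", protein = "p.Arg234Trp"),
    toy_record("S3", cdna = "c.800G>A", protein = "p.Gly267Asp"))
  out <- run_pgv_funnel(recs, open_cfg, n_samples = 3)
  expect_equal(out$unique_variants, dedupe(recs))
  expect_equal(nrow(run_pgv_funnel(recs[0, ], cfg)$records), 0)
})

test_that("VUS funnel reports the uncertain-significance surface", {
  t5 <- load_fixture("table5_vus")
  sc <- paper_scenario()
  run <- run_vus_funnel(sc$records, cfg,
                        pgv_positive = as.character(1:27))
  expect_equal(run$n_unique_vus, 21)
  expect_setequal(run$unique_variants$key, t5$key)
  expect_equal(length(run$mmr_unique), 10)
  mmr_per_gene <- table(run$unique_variants$gene[
    run$unique_variants$gene %in% c("MLH1", "MSH2", "MSH6", "PMS2")])
  expect_equal(as.vector(mmr_per_gene[c("MLH1", "MSH2", "MSH6", "PMS2")]),
               c(2, 2, 3, 3))
  expect_equal(length(run$vus_carriers), 35)
  expect_equal(length(run$carriers_with_pgv), 9)
  expect_equal(length(run$carriers_without_pgv), 26)
  # empty cohort: all counts zero
  empty <- run_vus_funnel(sc$records[0, ], cfg)
  expect_equal(empty$n_unique_vus, 0)
  expect_equal(length(empty$vus_carriers), 0)
})

test_that("funnel reports serialize to JSON and TSV", {
  recs <- toy_records(toy_record("S1", cdna = "c.900A>G",
                                 protein = "p.Lys300Glu"))
  out <- run_pgv_funnel(recs, cfg, n_samples = 1)
  jf <- withr::local_tempfile(fileext = ".json")
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_funnel_report(out, jf, tf)
  parsed <- jsonlite::read_json(jf, simplifyVector = TRUE)
  expect_equal(parsed$n_unique_variants, 1)
  expect_equal(nrow(read_tsv(tf)), nrow(out$stages))
})
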