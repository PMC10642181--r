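# oracle_combine / lattice_evidence come from helper-oracles.R

test_that("combining rules match the published worked examples", {
  expect_equal(acmg_combine(c("PVS1", "PS1"))$tier, "pathogenic")
  expect_equal(acmg_combine(c("PVS1", "PM2"))$tier, "likely_pathogenic")
  expect_equal(acmg_combine("PM2")$tier, "vus")
  expect_equal(acmg_combine("BA1")$tier, "benign")
  expect_equal(acmg_combine(c("BS1", "BP1"))$tier, "likely_benign")
  conflict <- acmg_combine(c("PVS1", "PS1", "BS1", "BS2"))
  expect_equal(conflict$tier, "vus")
  expect_true(conflict$conflict)
  # strict 2015 reading: PVS1 alone stays a VUS
  expect_equal(acmg_combine("PVS1")$tier, "vus")
  # conflict => vus, always
  expect_true(all(vapply(list(c("PVS1", "PM1", "BA1"), c("PS1", "PS2", "BP1", "BP2")),
                         function(cc) {
                           r <- acmg_combine(cc)
                           !r$conflict || r$tier == "vus"
                         }, logical(1))))
})

test_that("combine agrees with the rule-table oracle over the whole lattice", {
  grid <- expand.grid(pv = 0:1, ps = 0:3, pm = 0:5, pp = 0:5,
                      ba = 0:1, bs = 0:3, bp = 0:3)
  tiers <- character(nrow(grid))
  expected <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    ev <- lattice_evidence(g$pv, g$ps, g$pm, g$pp, g$ba, g$bs, g$bp)
    tiers[i] <- acmg_combine(ev)$tier   # totality: never errors
    expected[i] <- oracle_combine(g$pv, g$ps, g$pm, g$pp, g$ba, g$bs, g$bp)
  }
  expect_equal(tiers, expected)

  # monotonicity: without benign evidence, adding pathogenic evidence never
  # lowers the tier
  rank <- c(benign = 1, likely_benign = 2, vus = 3, likely_pathogenic = 4,
            pathogenic = 5)
  clean <- grid$ba == 0 & grid$bs == 0 & grid$bp == 0
  idx <- which(clean)
  key <- function(g) paste(g$pv, g$ps, g$pm, g$pp, sep = "-")
  tier_by_key <- setNames(tiers[idx], vapply(idx, function(i) key(grid[i, ]), ""))
  for (i in idx) {
    g <- grid[i, ]
    for (dim in c("pv", "ps", "pm", "pp")) {
      g2 <- g; g2[[dim]] <- g[[dim]] + 1L
      k2 <- key(g2)
      if (!is.na(tier_by_key[k2]))
        expect_gte(rank[tier_by_key[k2]], rank[tiers[i]])
    }
  }
})

test_that("evidence order never affects the verdict", {
  set.seed(3)
  for (rep in 1:50) {
    codes <- sample(acmg_codes()$code, sample(2:8, 1))
    a <- acmg_combine(codes)
    b <- acmg_combine(sample(codes))
    expect_equal(a$tier, b$tier)
    expect_equal(a$conflict, b$conflict)
  }
})

test_that("strength overrides change the effective counts", {
  # PS4 demoted to moderate: 1 strong + 1 moderate would be LP, but
  # two moderates alone are not
  expect_equal(acmg_combine(c("PS1", "PS4"))$tier, "pathogenic")
  expect_equal(acmg_combine(c("PS1", "PS4:moderate"))$tier,
               "likely_pathogenic")
  expect_error(evidence_set(c("PM2", "PM2")), class = "validation_error")
  expect_error(evidence_set("PX9"), class = "validation_error")
  expect_error(evidence_set("PM2:heroic"), class = "validation_error")
})

test_that("auto-assignment covers only the computable criteria", {
  panel <- default_panel()
  msh2 <- panel[panel$symbol == "MSH2", ]
  pold1 <- panel[panel$symbol == "POLD1", ]

  rec <- toy_records(toy_record("S1", gene = "MSH2", cdna = "c.187delG",
                                protein = "p.Val63fs"))
  ev <- auto_assign(rec[1, ], msh2)
  expect_true(all(c("PVS1", "PM2") %in% ev$code))

  # null variant in a non-LoF-mechanism gene: no PVS1
  rec <- toy_records(toy_record("S1", gene = "POLD1", cdna = "c.100delA",
                                protein = "p.Thr34fs"))
  expect_false("PVS1" %in% auto_assign(rec[1, ], pold1)$code)

  rec <- toy_records(toy_record("S1", cdna = "c.100A>G", maf = 0.12))
  expect_equal(auto_assign(rec[1, ], msh2)$code, "BA1")

  rec <- toy_records(toy_record("S1", cdna = "c.100A>G", maf = 0.005,
                                protein = "p.Lys34="))
  ev <- auto_assign(transform(rec[1, ], sift = "tolerated",
                              polyphen = "tolerated", grantham = "tolerated",
                              fathmm = "tolerated"), msh2)
  expect_setequal(ev$code, c("BP4", "BP7", "BS1"))

  rec <- toy_records(toy_record("S1", cdna = "c.200_202delGAT",
                                protein = "p.Asp67del", maf = NA))
  expect_true("PM4" %in% auto_assign(rec[1, ], msh2)$code)

  rec <- toy_records(toy_record("S1", cdna = "c.100A>G", maf = 0.005,
                                sift = "deleterious", polyphen = "deleterious",
                                grantham = "deleterious"))
  expect_true("PP3" %in% auto_assign(rec[1, ], msh2)$code)
})

test_that("cohort classification merges curated evidence over auto", {
  t3 <- load_fixture("table3_pgv")
  recs <- as_annotation_records(data.frame(
    sample_id = t3$patient_id, gene = t3$gene, cdna = t3$cdna,
    protein = t3$protein, location = "exonic", filter_status = "PASS",
    depth = 604L, maf = t3$maf, clinvar = t3$clinvar,
    stringsAsFactors = FALSE))
  uv <- dedupe(recs)
  curated <- data.frame(gene = t3$gene, cdna = t3$cdna, criteria = "",
                        tier = t3$acmg_tier, stringsAsFactors = FALSE)
  curated <- curated[!duplicated(variant_key(curated$gene, curated$cdna)), ]
  curated$key <- variant_key(curated$gene, curated$cdna)
  cls <- classify_cohort(uv, records = recs, curated = curated)
  expect_equal(nrow(pgv_set(cls)), 24)
  expect_equal(sort(unique(cls$tier)), c("likely_pathogenic", "pathogenic"))

  # curated criteria (not tier) merge over auto, curated wins per code
  uv1 <- dedupe(toy_records(toy_record("S1", gene = "MSH2",
                                       cdna = "c.187delG",
                                       protein = "p.Val63fs")))
  cur <- data.frame(gene = "MSH2", cdna = "c.187delG",
                    criteria = "PS1;PM2:supporting", tier = "",
                    stringsAsFactors = FALSE)
  cur$key <- variant_key(cur$gene, cur$cdna)
  cls1 <- classify_cohort(uv1, curated = cur)
  # PVS1 (auto) + PS1 (curated) -> pathogenic even with PM2 demoted
  expect_equal(cls1$tier, "pathogenic")
  expect_true(all(c("PVS1", "PS1") %in%
                    strsplit(cls1$criteria, ";")[[1]]))

  # vus-tier variants are excluded from the PGV set
  uv2 <- dedupe(toy_records(toy_record("S1", cdna = "c.500C>G",
                                       protein = "p.Pro167Ala", maf = 0.01)))
  cls2 <- classify_cohort(uv2)
  expect_equal(cls2$tier, "vus")
  expect_equal(nrow(pgv_set(cls2)), 0)

  # unknown curated keys warn and are ignored; empty cohort is empty
  expect_warning(classify_cohort(uv2, curated = cur), "unknown")
  expect_equal(nrow(classify_cohort(uv2[0, ])), 0)
})
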