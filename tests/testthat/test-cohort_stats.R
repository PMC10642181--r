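# fisher_enum_oracle comes from helper-oracles.R

test_that("carrier yields are distinct-patient counts with proportions", {
  calls <- data.frame(sample_id = c("1", "1", "2", "3"),
                      gene = c("MLH1", "PMS2", "MSH2", "APC"),
                      stringsAsFactors = FALSE)
  y <- pgv_yield(10, calls)
  expect_equal(y$count, 3)
  expect_equal(y$proportion, 0.3)
  expect_equal(pgv_yield(10, calls[0, ])$count, 0)
  expect_error(pgv_yield(0, calls), class = "degenerate_cohort_error")
})

test_that("MMR carrier count excludes EPCAM and never double-counts", {
  calls <- data.frame(sample_id = c("1", "1", "2", "3", "4"),
                      gene = c("MLH1", "APC", "EPCAM", "MSH6", "TP53"),
                      stringsAsFactors = FALSE)
  expect_equal(mmr_carrier_count(calls), 2)   # patients 1 and 3
  expect_equal(mmr_carrier_count(calls[calls$gene == "EPCAM", ]), 0)
})

test_that("per-gene distribution reports zeros for silent panel genes", {
  cls <- data.frame(gene = c("MSH2", "MSH2", "MLH1"),
                    tier = c("pathogenic", "likely_pathogenic", "pathogenic"),
                    stringsAsFactors = FALSE)
  d <- per_gene_distribution(cls)
  expect_equal(nrow(d), 14)
  expect_equal(d$total[d$gene == "MSH2"], 2)
  expect_equal(d$pathogenic[d$gene == "MSH2"], 1)
  expect_equal(d$total[d$gene == "STK11"], 0)
  expect_equal(sum(d$total), nrow(cls))
  expect_true(all(per_gene_distribution(cls[0, ])$total == 0))
})

test_that("novelty counts unique variants once", {
  uv <- data.frame(key = c("A", "A", "B", "C"),
                   gene = c("MLH1", "MLH1", "APC", "MSH2"),
                   reported_before = c("No (G>T only)", "No (G>T only)",
                                       "Yes", "No"),
                   stringsAsFactors = FALSE)
  nv <- novelty_count(uv)
  expect_equal(nv$n_novel, 2)        # A counted once, C
  expect_equal(nv$n_novel_mmr, 2)
  expect_equal(novelty_count(transform(uv, reported_before = "Yes"))$n_novel, 0)
})

test_that("IHC concordance matches the published per-patient calls", {
  t4 <- ihc_concordance(load_fixture("table4_ihc"))
  expect_equal(attr(t4, "n_concordant"), 6)
  # MLH1 lost but the variant is in MSH2: discordant
  expect_false(t4$concordant[t4$patient_id == "19"])
  # normal staining with a non-MMR variant supports the IHC finding
  expect_true(t4$concordant[t4$patient_id == "8"])
  # partial-loss rows: variant gene among the lost proteins
  expect_true(t4$concordant[t4$patient_id == "16"])
  expect_false(any(is.na(t4$concordant)))   # total over the fixture
})

test_that("Fisher two-sided p follows the minimum-likelihood convention", {
  # published age-category cross-tab
  t <- matrix(c(25, 2, 79, 1), 2)
  expect_equal(fisher_exact(t)$p, 0.156, tolerance = 5e-3)
  expect_equal(fisher_exact(t)$p, fisher_enum_oracle(t), tolerance = 1e-12)
  expect_equal(fisher_exact(matrix(1, 2, 2))$p, 1)
  expect_error(fisher_exact(matrix(c(0, 0, 1, 2), 2)),
               class = "degenerate_table_error")
})

test_that("Fisher p equals the enumeration oracle on random small tables", {
  set.seed(19)
  for (rep in 1:200) {
    t <- matrix(sample(0:12, 4, replace = TRUE), 2)
    if (any(rowSums(t) == 0) || any(colSums(t) == 0)) next
    expect_equal(fisher_exact(t)$p, fisher_enum_oracle(t), tolerance = 1e-10,
                 label = paste(t, collapse = ","))
  }
})

test_that("Yates-corrected chi-squared matches the closed form", {
  t <- matrix(c(15, 12, 39, 41), 2)
  res <- chi_squared_yates(t)
  expect_equal(res$p, 0.697, tolerance = 5e-4)
  hand <- function(t) {
    n <- sum(t)
    # corrected difference clamps at zero (no over-correction)
    d <- max(0, abs(t[1, 1] * t[2, 2] - t[1, 2] * t[2, 1]) - n / 2)
    n * d^2 / (sum(t[1, ]) * sum(t[2, ]) * sum(t[, 1]) * sum(t[, 2]))
  }
  expect_equal(res$statistic, hand(t))
  set.seed(23)
  for (rep in 1:50) {
    t <- matrix(sample(5:60, 4, replace = TRUE), 2)
    expect_equal(chi_squared_yates(t)$statistic, hand(t), tolerance = 1e-12)
  }
  # perfectly proportional table: statistic clamps at zero, p = 1
  prop <- chi_squared_yates(matrix(c(10, 20, 30, 60), 2))
  expect_equal(prop$statistic, 0, tolerance = 1e-12)
  expect_equal(prop$p, 1)
  expect_error(chi_squared_yates(matrix(1, 2, 3)),
               class = "degenerate_table_error")
})

test_that("Wilcoxon rank-sum: exact and approximate routes agree", {
  expect_equal(wilcoxon_rank_sum(c(1, 1, 1), c(1, 1, 1))$p, 1)
  set.seed(31)
  x <- round(rnorm(8, 10, 3), 6); y <- round(rnorm(8, 11, 3), 6)
  exact <- wilcoxon_rank_sum(x, y)
  expect_equal(exact$method, "wilcoxon_exact")
  approx <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                                correct = TRUE)$p.value)
  expect_lt(abs(exact$p - approx), 0.05)
  # symmetry
  expect_equal(wilcoxon_rank_sum(x, y)$p, wilcoxon_rank_sum(y, x)$p)
  # exact p against direct enumeration of all group assignments
  xs <- c(1.2, 3.4, 5.1, 7.9); ys <- c(2.2, 4.6, 6.3, 8.8)
  pool <- c(xs, ys); n <- length(xs)
  ranks <- rank(pool)
  w_obs <- sum(ranks[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(length(pool), n)
  ws <- apply(combos, 2, function(i) sum(ranks[i]) - n * (n + 1) / 2)
  mu <- n * (length(ys)) / 2
  p_enum <- if (w_obs >= mu) 2 * mean(ws >= w_obs) else 2 * mean(ws <= w_obs)
  p_enum <- min(1, p_enum)
  expect_equal(wilcoxon_rank_sum(xs, ys)$p, p_enum, tolerance = 1e-12)
  expect_error(wilcoxon_rank_sum(numeric(), 1:3),
               class = "degenerate_group_error")
})

test_that("association tests annotate significance at 0.05", {
  res <- association_tests(load_fixture("table2_aggregates"))
  expect_true(all(res$p >= 0 & res$p <= 1))
  expect_false(any(res$significant))
  expect_equal(res$method[res$variable == "gender"], "chi_squared_yates")
})

test_that("the summary report round-trips through its own reader", {
  sc <- paper_scenario()
  run <- run_triage(sc$records, sc$registry, sc$curated, sc$ledger,
                    aggregates = load_fixture("table2_aggregates"))
  jf <- withr::local_tempfile(fileext = ".json")
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_summary(run$summary, jf, tf)
  back <- read_summary(jf)
  expect_equal(back$n_patients, 107)
  expect_equal(back$post_verification$carriers,
               run$summary$post_verification$carriers)
  expect_equal(nrow(read_tsv(tf)), 14)
  # deterministic across repeated runs
  run2 <- run_triage(sc$records, sc$registry, sc$curated, sc$ledger)
  expect_equal(run2$summary$pre_verification, run$summary$pre_verification)
  expect_equal(run2$summary$vus, run$summary$vus)
})
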