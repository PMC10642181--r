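# Independent oracles shared by the unit and acceptance tests. Each is coded
# from the rule statement directly, not from the package's implementation.

# ACMG combining table as flat boolean algebra over strength counts
oracle_combine <- function(pv, ps, pm, pp, ba, bs, bp) {
  P <- (pv >= 1 & (ps >= 1 | pm >= 2 | (pm == 1 & pp == 1) | pp >= 2)) |
    ps >= 2 |
    (ps == 1 & (pm >= 3 | (pm == 2 & pp >= 2) | (pm == 1 & pp >= 4)))
  LP <- (pv >= 1 & pm == 1) | (ps == 1 & pm >= 1 & pm <= 2) |
    (ps == 1 & pp >= 2) | pm >= 3 | (pm == 2 & pp >= 2) | (pm == 1 & pp >= 4)
  B <- ba >= 1 | bs >= 2
  LB <- (bs == 1 & bp == 1) | bp >= 2
  if ((P | LP) & (B | LB)) return("vus")
  if (P) return("pathogenic")
  if (LP) return("likely_pathogenic")
  if (B) return("benign")
  if (LB) return("likely_benign")
  "vus"
}

# an evidence set realising given strength counts with distinct codes
lattice_evidence <- function(pv, ps, pm, pp, ba, bs, bp) {
  codes <- c(if (pv) "PVS1",
             if (ps > 0) paste0("PS", seq_len(ps)),
             if (pm > 0) paste0("PM", seq_len(pm)),
             if (pp > 0) paste0("PP", seq_len(pp)),
             if (ba) "BA1",
             if (bs > 0) paste0("BS", seq_len(bs)),
             if (bp > 0) paste0("BP", seq_len(bp)))
  evidence_set(codes)
}

# two-sided Fisher p on a 2x2 table by full hypergeometric enumeration:
# sum of probabilities of all tables with the observed margins whose point
# probability does not exceed the observed one
fisher_enum_oracle <- function(t) {
  r1 <- sum(t[1, ]); r2 <- sum(t[2, ]); c1 <- sum(t[, 1])
  k <- max(0, c1 - r2):min(r1, c1)
  pmf <- stats::dhyper(k, r1, r2, c1)
  stopifnot(abs(sum(pmf) - 1) < 1e-9)   # enumerated pmf is a distribution
  obs <- stats::dhyper(t[1, 1], r1, r2, c1)
  sum(pmf[pmf <= obs * (1 + 1e-7)])
}
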