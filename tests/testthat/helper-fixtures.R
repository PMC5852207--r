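# Fixtures are built in code at test time; nothing is read from disk
# except files the tests themselves write to tempdir().

# A minimal weight configuration. By default: two SNPs (OR 2 and 4), no
# haplotype loci, H(X_X) = ln(3) and all other diplotype weights 0 -- the
# shape used by the hand-computed score checks.
toy_weights <- function(snp_or = c(snpA = 2, snpB = 4),
                        dip_or = c(DR3_DR4 = 1, DR4_DR4 = 1, DR3_DR3 = 1,
                                   DR4_X = 1, DR3_X = 1, X_X = 3),
                        hap_or = NULL,
                        chromosome = NULL) {
  if (is.null(chromosome))
    chromosome <- setNames(rep("1", length(snp_or)), names(snp_or))
  new("GrsWeights",
      snpBeta = log(snp_or),
      diplotypeBeta = log(dip_or)[c("DR3_DR4", "DR4_DR4", "DR3_DR3",
                                    "DR4_X", "DR3_X", "X_X")],
      haplotypeBeta = if (is.null(hap_or)) numeric(0)
                      else log(hap_or)[c("non_dq6", "a24", "non_b57")],
      tagSnps = c(dr3 = "rs2187668", dr4 = "rs7454108", dq6 = "rs3129889",
                  a24 = "rs1264813", b57 = "rs2395029"),
      riskAllele = setNames(rep("A", length(snp_or)), names(snp_or)),
      chromosome = chromosome)
}

# A small cohort on the full default panel with every call present;
# individual cells can then be knocked out per test.
full_call_cohort <- function(n = 3, dosage_value = 1) {
  pan <- defaultPanel()
  dos <- matrix(dosage_value, nrow(pan), n,
                dimnames = list(pan$snp_id, sprintf("s%02d", seq_len(n))))
  meta <- data.frame(sample_id = colnames(dos), group = "control",
                     sex = "female", race = "CAU",
                     ethnicity = "non_hispanic",
                     age_at_diagnosis = NA_real_,
                     age_at_donation = 30, aab_count = 0)
  GrsCohort(dos, pan, meta)
}

write_toy_weight_json <- function(path,
                                  snp_or = list(list(snp_id = "snpA",
                                                     risk_allele = "A",
                                                     or = 2.30,
                                                     chromosome = "1")),
                                  drop_category = NULL) {
  dip <- list(DR3_DR4 = 9.95, DR4_DR4 = 2.3, DR3_DR3 = 30.56,
              DR4_X = 1.69, DR3_X = 0.75, X_X = 1)
  if (!is.null(drop_category)) dip[[drop_category]] <- NULL
  cfg <- list(snps = snp_or,
              haplotype_or = list(non_dq6 = 7.52, a24 = 0.72,
                                  non_b57 = 2.91),
              hla_diplotype_or = dip,
              tag_snps = list(dr3 = "rs2187668", dr4 = "rs7454108",
                              dq6 = "rs3129889", a24 = "rs1264813",
                              b57 = "rs2395029"))
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  path
}

# --- independent oracles ---------------------------------------------------

# two-sided Fisher p by exhaustive enumeration over all tables with the
# observed margins, using log-binomial-coefficient arithmetic
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  logp <- function(x) lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1)
  all_lp <- vapply(lo:hi, logp, numeric(1))
  obs <- logp(a)
  sum(exp(all_lp[all_lp <= obs + 1e-7]))
}

# AUC as the explicit all-pairs statistic
auc_oracle <- function(scores, labels) {
  cs <- scores[labels == 1]; ct <- scores[labels == 0]
  tot <- 0
  for (x in cs) for (y in ct)
    tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(cs) * length(ct))
}

balanced_accuracy_at <- function(scores, labels, t) {
  (mean(scores[labels == 1] >= t) + mean(scores[labels == 0] < t)) / 2
}
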