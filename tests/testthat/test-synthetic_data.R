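test_that("default group models carry the published frequencies", {
  m <- defaultGroupModels("CAU")
  expect_equal(m$control$diplotype_freqs[["X_X"]], 0.5625,
               tolerance = 1e-3)
  expect_equal(m$t1d$diplotype_freqs[["DR3_DR4"]], 0.2636,
               tolerance = 1e-3)
  expect_equal(m$t1d$snp_freqs[["rs2476601"]], 0.1542)
  a <- defaultGroupModels("AFR")
  expect_equal(a$t1d$snp_freqs[["rs2664170"]], 0.5882)
  # every model's diplotype distribution is a proper distribution
  for (mod in c(m, a))
    expect_equal(sum(mod$diplotype_freqs), 1, tolerance = 1e-9)
  # relatives interpolate between control and case frequencies
  expect_true(m$control$snp_freqs[["rs689"]] <
                m$relative2$snp_freqs[["rs689"]])
  expect_true(m$relative2$snp_freqs[["rs689"]] <
                m$relative1$snp_freqs[["rs689"]])
  expect_true(m$relative1$snp_freqs[["rs689"]] <
                m$t1d$snp_freqs[["rs689"]])
  expect_error(defaultGroupModels("XYZ"), "unsupported")
})

test_that("simulation is reproducible and honours degenerate settings", {
  cfg <- simulationConfig(c(t1d = 30, control = 30), seed = 99)
  a <- simulateCohort(defaultGroupModels("CAU"), cfg)
  b <- simulateCohort(defaultGroupModels("CAU"), cfg)
  expect_identical(dosages(a), dosages(b))
  expect_identical(sampleData(a), sampleData(b))
  # zero-size groups yield no samples
  c0 <- simulateCohort(defaultGroupModels("CAU"),
                       simulationConfig(c(t1d = 0, control = 10), seed = 1))
  expect_false(any(sampleData(c0)$group == "t1d"))
  # a fixed allele: every dosage is 2
  m <- defaultGroupModels("CAU")["control"]
  m$control$snp_freqs[] <- 1
  cf <- simulateCohort(m, simulationConfig(c(control = 20), seed = 2))
  expect_true(all(dosages(cf)["rs689", ] == 2))
})

test_that("simulated allele frequencies recover the configured values", {
  n <- 5000
  coh <- simulateCohort(defaultGroupModels("CAU")["control"],
                        simulationConfig(c(control = n), seed = 101))
  model <- defaultGroupModels("CAU")$control
  d <- dosages(coh)
  sex <- sampleData(coh)$sex
  pan <- snpPanel(coh)
  for (s in names(model$snp_freqs)) {
    p <- model$snp_freqs[[s]]
    if (pan$chromosome[match(s, pan$snp_id)] == "X") {
      female <- sex == "female"
      phat <- mean(d[s, female]) / 2
      se <- sqrt(p * (1 - p) / (2 * sum(female)))
    } else {
      phat <- mean(d[s, ]) / 2
      se <- sqrt(p * (1 - p) / (2 * n))
    }
    expect_lt(abs(phat - p), 3 * se + 1e-9)
  }
})

test_that("autosomal genotypes respect Hardy-Weinberg proportions", {
  n <- 5000
  coh <- simulateCohort(defaultGroupModels("CAU")["control"],
                        simulationConfig(c(control = n), seed = 7))
  pan <- snpPanel(coh)
  auto <- pan$snp_id[!pan$is_hla_tag & pan$chromosome != "X"]
  d <- dosages(coh)
  fails <- 0L
  for (s in auto) {
    g <- tabulate(d[s, ] + 1, 3)
    p <- sum(g * c(0, 1, 2)) / (2 * n)
    expt <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
    keep <- expt > 0
    stat <- sum((g[keep] - expt[keep])^2 / expt[keep])
    if (stat > qchisq(0.999, df = 1)) fails <- fails + 1L
  }
  expect_lte(fails, ceiling(0.05 * length(auto)))
})

test_that("the age-at-diagnosis model recovers its log-normal parameters", {
  n <- 10000
  coh <- simulateCohort(defaultGroupModels("CAU")["t1d"],
                        simulationConfig(c(t1d = n), seed = 5))
  ages <- sampleData(coh)$age_at_diagnosis
  expect_false(anyNA(ages))
  sdlog <- log(2.18)
  expect_lt(abs(mean(log(ages)) - log(8.94)), 3 * sdlog / sqrt(n))
  expect_lt(abs(sd(log(ages)) - sdlog), 3 * sdlog / sqrt(2 * n))
})

test_that("a null liability (all OR = 1) leaves case frequencies at control values", {
  w <- toy_weights(
    snp_or = c(rs2476601 = 1, rs689 = 1),
    hap_or = c(non_dq6 = 1, a24 = 1, non_b57 = 1))
  pop <- defaultGroupModels("CAU")$control
  coh <- simulateLiabilityFamily(pop, w, 0.3,
                                 simulationConfig(c(t1d = 800, control = 800),
                                                  seed = 23))
  d <- dosages(coh)
  grp <- sampleData(coh)$group
  for (s in c("rs2476601", "rs689")) {
    p_case <- mean(d[s, grp == "t1d"]) / 2
    p_true <- pop$snp_freqs[[s]]
    se <- sqrt(p_true * (1 - p_true) / (2 * 800))
    expect_lt(abs(p_case - p_true), 4 * se)
  }
})

test_that("a single-locus liability reproduces its closed-form allele odds ratio", {
  beta <- log(4); p <- 0.3; prev <- 0.05
  w <- toy_weights(
    snp_or = c(rsTOY = 4),
    dip_or = c(DR3_DR4 = 1, DR4_DR4 = 1, DR3_DR3 = 1, DR4_X = 1,
               DR3_X = 1, X_X = 1),
    hap_or = c(non_dq6 = 1, a24 = 1, non_b57 = 1))
  pop <- groupModel("control",
                    defaultGroupModels("CAU")$control$diplotype_freqs,
                    defaultGroupModels("CAU")$control$haplotype_freqs,
                    c(rsTOY = p))
  pan <- rbind(defaultPanel()[defaultPanel()$is_hla_tag, ],
               data.frame(snp_id = "rsTOY", locus = "1p00", gene = "TOY",
                          risk_allele = "A", chromosome = "1",
                          is_hla_tag = FALSE, role = "nonhla"))
  # closed form: HWE genotype mix, logistic penetrance, alpha calibrated
  hwe <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  alpha <- uniroot(function(a) sum(hwe * plogis(a + beta * 0:2)) - prev,
                   c(-30, 30), tol = 1e-12)$root
  pi_s <- plogis(alpha + beta * 0:2)
  p1 <- sum(0:2 * pi_s * hwe) / (2 * sum(pi_s * hwe))
  p0 <- sum(0:2 * (1 - pi_s) * hwe) / (2 * sum((1 - pi_s) * hwe))
  or_true <- (p1 / (1 - p1)) / (p0 / (1 - p0))

  n <- 5000
  coh <- simulateLiabilityFamily(pop, w, prev,
                                 simulationConfig(c(t1d = n, control = n),
                                                  seed = 31),
                                 panel = pan)
  d <- dosages(coh); grp <- sampleData(coh)$group
  a <- sum(d["rsTOY", grp == "t1d"]); b <- 2 * n - a
  cc <- sum(d["rsTOY", grp == "control"]); dd <- 2 * n - cc
  est <- oddsRatioFromCounts(a, b, cc, dd)
  expect_gt(or_true, est$ci_low)
  expect_lt(or_true, est$ci_high)
  # and the closed-form value sits near the nominal per-allele OR of 4
  expect_lt(abs(or_true - 4) / 4, 0.15)
})

test_that("liability families show the expected dilution of risk", {
  coh <- simulateLiabilityFamily(
    defaultGroupModels("CAU")$control, defaultWeights(), 0.2,
    simulationConfig(c(t1d = 600, relative1 = 600, relative2 = 600,
                       control = 600), seed = 3))
  sc <- scoreCohort(applyQC(coh), defaultWeights())
  means <- tapply(sc$grs, sampleData(coh)$group, mean)
  expect_gt(means[["t1d"]], means[["relative1"]])
  expect_gt(means[["relative1"]], means[["relative2"]])
  expect_gt(means[["relative2"]], means[["control"]])
})

test_that("unattainable prevalence targets are rejected with a clear error", {
  w <- toy_weights(snp_or = c(rs2476601 = 1),
                   hap_or = c(non_dq6 = 1, a24 = 1, non_b57 = 1))
  expect_error(simulateLiabilityFamily(
    defaultGroupModels("CAU")$control, w, 0.4999,
    simulationConfig(c(t1d = 5, control = 5), seed = 1)), NA)
  expect_error(simulateLiabilityFamily(
    defaultGroupModels("CAU")$control, w, 0.6,
    simulationConfig(c(t1d = 5, control = 5), seed = 1)), "prevalence")
})
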