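# Synthetic cohort generation. Two generative modes:
#
# * group_frequencies: each study group (control, relatives, at-risk, T1D)
#   has its own categorical diplotype distribution, haplotype frequencies
#   and per-SNP risk-allele frequencies; subjects are drawn independently,
#   SNP genotypes under Hardy-Weinberg equilibrium.  Default frequencies
#   are the published group-specific values (table2Reference()).
#
# * liability_family: genotypes are drawn from population (control)
#   frequencies, disease status follows a logistic liability on the score
#   numerator with the intercept calibrated to a target prevalence, and
#   relatives are produced by Mendelian transmission through simulated
#   parents - the principled mechanism behind the observed dilution of
#   risk in first- and second-degree relatives.
#
# Loci are simulated independently (no linkage disequilibrium); this is
# the generator's main simplification relative to real cohorts.

.AGE_BIN_BREAKS <- c(0.5, 8, 16, 40)

#' Construct a group generative model
#'
#' @param label group label, one of `control`, `relative2`, `relative1`,
#'   `at_risk`, `t1d`.
#' @param diplotype_freqs named numeric over the six diplotype categories
#'   (subject-level probabilities; must sum to 1 within 0.002, tolerance
#'   for published rounded values).
#' @param haplotype_freqs named numeric over `non_dq6`, `a24`, `non_b57`
#'   (haplotype frequencies, risk orientation).
#' @param snp_freqs named numeric of risk-allele frequencies per SNP.
#' @param age_model `list(geometric_mean=, geometric_sd=)` for
#'   age-at-diagnosis (years; log-normal), or `NULL` for non-patients.
#' @param age_bin_probs optional 3 x 6 matrix of age-bin probabilities per
#'   diplotype category (columns), for the age-by-diplotype sampling mode.
#' @param race race label attached to simulated subjects.
#' @return list of class `"GroupModel"`.
#' @export
groupModel <- function(label, diplotype_freqs, haplotype_freqs, snp_freqs,
                       age_model = NULL, age_bin_probs = NULL,
                       race = "CAU") {
  freqs <- c(diplotype_freqs, haplotype_freqs, snp_freqs)
  if (any(freqs < 0 | freqs > 1))
    stop("frequencies must lie in [0, 1]")
  if (abs(sum(diplotype_freqs) - 1) > 0.002)
    stop("diplotype frequencies must sum to 1 (got ",
         round(sum(diplotype_freqs), 4), ")")
  if (!setequal(names(diplotype_freqs), .DIPLOTYPE_LEVELS))
    stop("diplotype_freqs must cover the six categories")
  structure(list(label = label,
                 diplotype_freqs =
                   diplotype_freqs[.DIPLOTYPE_LEVELS] /
                     sum(diplotype_freqs),
                 haplotype_freqs = haplotype_freqs[.HAPLOTYPE_LEVELS],
                 snp_freqs = snp_freqs,
                 age_model = age_model,
                 age_bin_probs = age_bin_probs,
                 race = race),
            class = "GroupModel")
}

#' Default group models from the published frequencies
#'
#' Case and control models take the published group-specific diplotype,
#' haplotype and risk-allele frequencies verbatim (see
#' [table2Reference()]); at-risk relatives (two or more autoantibodies)
#' reuse the case frequencies, reflecting their near-patient risk
#' profile.  No frequencies are published for unaffected relatives, so
#' relative models interpolate between control and case frequencies with
#' mixing weight equal to the kinship coefficient of relationship: 1/2
#' for first-degree, 1/4 for second-degree.  The patient age-at-diagnosis
#' model is log-normal with geometric mean 8.94 years and geometric SD
#' 2.18.
#'
#' @param race `"CAU"` or `"AFR"`.
#' @return named list of [groupModel()] objects: `control`, `relative2`,
#'   `relative1`, `at_risk`, `t1d`.
#' @examples
#' m <- defaultGroupModels("CAU")
#' m$control$diplotype_freqs[["X_X"]]  # 0.5625
#' @export
defaultGroupModels <- function(race = c("CAU", "AFR")) {
  race <- tryCatch(match.arg(race),
                   error = function(e) stop("unsupported race: ", race[1],
                                            call. = FALSE))
  ref <- table2Reference()
  ref <- ref[ref$race == race, ]
  pull <- function(kind, col) {
    v <- ref[ref$kind == kind, col]
    names(v) <- ref$marker[ref$kind == kind]
    v
  }
  dip_t1d <- pull("diplotype", "freq_t1d")
  dip_ctl <- pull("diplotype", "freq_control")
  hap_t1d <- pull("haplotype", "freq_t1d")
  hap_ctl <- pull("haplotype", "freq_control")
  snp_t1d <- pull("snp", "freq_t1d")
  snp_ctl <- pull("snp", "freq_control")
  age <- list(geometric_mean = 8.94, geometric_sd = 2.18)
  bins <- prop.table(table1Reference(), margin = 2)
  mix <- function(label, w) {
    dip <- (1 - w) * dip_ctl + w * dip_t1d
    groupModel(label,
               dip / sum(dip),
               (1 - w) * hap_ctl + w * hap_t1d,
               (1 - w) * snp_ctl + w * snp_t1d,
               race = race)
  }
  list(control = groupModel("control", dip_ctl, hap_ctl, snp_ctl,
                            race = race),
       relative2 = mix("relative2", 0.25),
       relative1 = mix("relative1", 0.5),
       at_risk = groupModel("at_risk", dip_t1d, hap_t1d, snp_t1d,
                            race = race),
       t1d = groupModel("t1d", dip_t1d, hap_t1d, snp_t1d,
                        age_model = age, age_bin_probs = bins,
                        race = race))
}

#' Simulation configuration
#'
#' @param group_sizes named integer vector, samples per group (groups not
#'   named get zero).
#' @param seed integer seed; the same seed reproduces the cohort exactly.
#' @param sex_ratio fraction male, default 0.5.
#' @param age_by_diplotype draw patient ages by first sampling an age bin
#'   from the model's per-diplotype bin probabilities (uniform within the
#'   bin) instead of the log-normal model; ties age to HLA only.
#' @param donation_age_range uniform window (years) for age at donation.
#' @param hispanic_fraction probability of a Hispanic ethnicity label.
#' @param p_aab_relative probability a non-patient carries one
#'   autoantibody (labels only; at-risk subjects are fixed at 2).
#' @return list of class `"SimulationConfig"`.
#' @export
simulationConfig <- function(group_sizes, seed = 1L, sex_ratio = 0.5,
                             age_by_diplotype = FALSE,
                             donation_age_range = c(5, 50),
                             hispanic_fraction = 0.135,
                             p_aab_relative = 0.1) {
  if (is.null(names(group_sizes)) || any(group_sizes < 0))
    stop("group_sizes must be a named vector of non-negative counts")
  structure(list(group_sizes = group_sizes, seed = as.integer(seed),
                 sex_ratio = sex_ratio,
                 age_by_diplotype = age_by_diplotype,
                 donation_age_range = donation_age_range,
                 hispanic_fraction = hispanic_fraction,
                 p_aab_relative = p_aab_relative),
            class = "SimulationConfig")
}

.DIP_TAG_DOSE <- matrix(
  c(1, 1,   0, 2,   2, 0,   0, 1,   1, 0,   0, 0), nrow = 2,
  dimnames = list(c("dr3", "dr4"), .DIPLOTYPE_LEVELS))

#' Simulate a cohort under the group-frequency model
#'
#' Per sample: the diplotype category is a categorical draw (the DR3/DR4
#' tag dosages follow from it, so simulated cohorts are conflict-free);
#' each haplotype locus sums two independent haplotype draws; each
#' autosomal SNP dosage is Binomial(2, p) (Hardy-Weinberg); X-linked SNPs
#' in males are a single draw recorded as 0/2.  Patient ages at diagnosis
#' are log-normal, or bin-sampled per diplotype when
#' `age_by_diplotype = TRUE`.
#'
#' @param models named list of [groupModel()] objects (e.g.
#'   [defaultGroupModels()]).
#' @param config a [simulationConfig()].
#' @param panel SNP panel, default [defaultPanel()].
#' @return A [GrsCohort-class].
#' @examples
#' coh <- simulateCohort(defaultGroupModels("CAU"),
#'                       simulationConfig(c(t1d = 10, control = 10),
#'                                        seed = 42))
#' table(sampleData(coh)$group)
#' @export
simulateCohort <- function(models, config, panel = defaultPanel()) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  sizes <- config$group_sizes[config$group_sizes > 0]
  unknown <- setdiff(names(sizes), names(models))
  if (length(unknown))
    stop("no model for group(s): ", paste(unknown, collapse = ", "))
  parts <- lapply(names(sizes), function(g)
    .simulate_group(models[[g]], sizes[[g]], config, panel))
  if (!length(parts)) {
    dos <- matrix(numeric(), nrow(panel), 0,
                  dimnames = list(panel$snp_id, character()))
    return(GrsCohort(dos, panel))
  }
  dosage <- do.call(cbind, lapply(parts, `[[`, "dosage"))
  meta <- do.call(rbind, lapply(parts, `[[`, "meta"))
  GrsCohort(dosage, panel = panel, metadata = meta)
}

.simulate_group <- function(model, n, config, panel) {
  ids <- sprintf("%s_%s_%04d", model$race, model$label, seq_len(n))
  sex <- ifelse(runif(n) < config$sex_ratio, "male", "female")
  cat_draw <- sample(.DIPLOTYPE_LEVELS, n, replace = TRUE,
                     prob = model$diplotype_freqs)
  hap <- vapply(.HAPLOTYPE_LEVELS, function(h)
    rbinom(n, 2, model$haplotype_freqs[[h]]), numeric(n))
  hap <- matrix(hap, nrow = n,
                dimnames = list(NULL, .HAPLOTYPE_LEVELS))
  dosage <- matrix(NA_real_, nrow(panel), n,
                   dimnames = list(panel$snp_id, ids))
  role <- panel$role
  dosage[role == "dr3_tag", ] <- .DIP_TAG_DOSE["dr3", cat_draw]
  dosage[role == "dr4_tag", ] <- .DIP_TAG_DOSE["dr4", cat_draw]
  dosage[role == "dq6_tag", ] <- 2 - hap[, "non_dq6"]
  dosage[role == "a24_tag", ] <- hap[, "a24"]
  dosage[role == "b57_tag", ] <- 2 - hap[, "non_b57"]
  for (s in names(model$snp_freqs)) {
    p <- model$snp_freqs[[s]]
    on_x <- panel$chromosome[match(s, panel$snp_id)] == "X"
    d <- rbinom(n, 2, p)
    if (on_x) {
      male <- sex == "male"
      d[male] <- 2 * rbinom(sum(male), 1, p)
    }
    dosage[s, ] <- d
  }
  age_dx <- rep(NA_real_, n)
  if (model$label == "t1d") {
    if (config$age_by_diplotype && !is.null(model$age_bin_probs)) {
      bin <- vapply(cat_draw, function(cat)
        sample.int(3, 1, prob = model$age_bin_probs[, cat]), integer(1))
      age_dx <- runif(n, .AGE_BIN_BREAKS[bin], .AGE_BIN_BREAKS[bin + 1])
    } else if (!is.null(model$age_model)) {
      age_dx <- rlnorm(n, log(model$age_model$geometric_mean),
                       log(model$age_model$geometric_sd))
    }
  }
  aab <- switch(model$label,
                t1d = rep(2, n),
                at_risk = rep(2, n),
                rbinom(n, 1, config$p_aab_relative))
  meta <- data.frame(
    sample_id = ids, group = model$label, sex = sex,
    race = model$race,
    ethnicity = ifelse(runif(n) < config$hispanic_fraction,
                       "hispanic", "non_hispanic"),
    age_at_diagnosis = age_dx,
    age_at_donation = runif(n, config$donation_age_range[1],
                            config$donation_age_range[2]),
    aab_count = aab, stringsAsFactors = FALSE)
  list(dosage = dosage, meta = meta)
}

# ---- liability-threshold family mode ------------------------------------

# Internal allele-level representation: one row per locus.  Locus 1 is the
# HLA class-II haplotype (1 = DR3, 2 = DR4, 3 = X); the three haplotype
# loci and the SNPs are 0/1 risk-allele indicators.  Individuals are a
# pair of allele matrices (maternal, paternal); X-linked rows in males
# carry the maternal allele in both slots and count as 0 or 2.

.lia_loci <- function(model, weights) {
  dip <- model$diplotype_freqs
  hx <- sqrt(dip[["X_X"]])
  h3 <- if (hx > 0) dip[["DR3_X"]] / (2 * hx) else NA
  h4 <- if (hx > 0) dip[["DR4_X"]] / (2 * hx) else NA
  if (!is.finite(h3) || !is.finite(h4))
    stop("cannot derive haplotype frequencies: X_X frequency is 0")
  tot <- h3 + h4 + hx
  snp_ids <- names(weights@snpBeta)
  list(h_classII = c(dr3 = h3, dr4 = h4, x = hx) / tot,
       p = c(model$haplotype_freqs[.HAPLOTYPE_LEVELS],
             model$snp_freqs[snp_ids]),
       on_x = c(rep(FALSE, 3),
                weights@chromosome[snp_ids] == "X"),
       snp_ids = snp_ids)
}

.lia_draw <- function(loci, n, sex) {
  L <- length(loci$p) + 1
  draw_slot <- function() {
    m <- matrix(0, L, n, dimnames = list(c("classII", names(loci$p)), NULL))
    m[1, ] <- sample.int(3, n, replace = TRUE, prob = loci$h_classII)
    m[-1, ] <- rbinom((L - 1) * n, 1, rep(loci$p, times = n))
    m
  }
  m1 <- draw_slot(); m2 <- draw_slot()
  male <- sex == "male"
  if (any(loci$on_x) && any(male))  # hemizygous: one X draw, duplicated
    m2[c(FALSE, loci$on_x), male] <- m1[c(FALSE, loci$on_x), male]
  list(m1 = m1, m2 = m2)
}

.lia_transmit <- function(parent, j, n_child) {
  # one gamete per child from parent individual(s) j (recycled)
  L <- nrow(parent$m1)
  pick <- matrix(runif(L * n_child) < 0.5, L, n_child)
  a1 <- parent$m1[, j, drop = FALSE]
  a2 <- parent$m2[, j, drop = FALSE]
  out <- a1
  out[pick] <- a2[pick]
  out
}

.lia_child <- function(mother, father, jm, jf, sex, loci) {
  g_m <- .lia_transmit(mother, jm, length(jm))
  g_f <- .lia_transmit(father, jf, length(jf))
  male <- sex == "male"
  xrow <- c(FALSE, loci$on_x)
  if (any(xrow) && any(male))
    g_f[xrow, male] <- g_m[xrow, male]   # sons: X is maternal only
  list(m1 = g_m, m2 = g_f)
}

.lia_numerator <- function(ind, sex, loci, weights) {
  dos <- ind$m1[-1, , drop = FALSE] + ind$m2[-1, , drop = FALSE]
  beta <- c(weights@haplotypeBeta, weights@snpBeta)
  num <- as.numeric(crossprod(dos, beta))
  d3 <- (ind$m1[1, ] == 1) + (ind$m2[1, ] == 1)
  d4 <- (ind$m1[1, ] == 2) + (ind$m2[1, ] == 2)
  cat_draw <- imputeDiplotype(d3, d4)$category
  num + weights@diplotypeBeta[as.character(cat_draw)]
}

.lia_to_dosage <- function(ind, ids, panel) {
  d3 <- (ind$m1[1, ] == 1) + (ind$m2[1, ] == 1)
  d4 <- (ind$m1[1, ] == 2) + (ind$m2[1, ] == 2)
  body <- ind$m1[-1, , drop = FALSE] + ind$m2[-1, , drop = FALSE]
  dosage <- matrix(NA_real_, nrow(panel), ncol(body),
                   dimnames = list(panel$snp_id, ids))
  dosage[panel$role == "dr3_tag", ] <- d3
  dosage[panel$role == "dr4_tag", ] <- d4
  dosage[panel$role == "dq6_tag", ] <- 2 - body[1, ]
  dosage[panel$role == "a24_tag", ] <- body[2, ]
  dosage[panel$role == "b57_tag", ] <- 2 - body[3, ]
  dosage[rownames(body)[-(1:3)], ] <- body[-(1:3), , drop = FALSE]
  dosage
}

#' Simulate case, relative and control groups under a liability model
#'
#' Genotypes are drawn from the population (control) frequencies; disease
#' follows `P(case | genotype) = logistic(alpha + numerator)` where the
#' numerator is the unnormalised score (`sum beta_i s_i + H`), with
#' `alpha` calibrated by root-finding on a Monte-Carlo genotype pool so
#' the marginal case rate matches `prevalence` within 2%.  Cases are
#' obtained by Bernoulli thinning of simulated children; first-degree
#' relatives are siblings drawn from the same simulated parents;
#' second-degree relatives are children of a sibling with a random
#' population mate (one extra meiosis).
#'
#' @param populationModel a [groupModel()] with population (control)
#'   frequencies.
#' @param weights a [GrsWeights-class]; its betas define the liability.
#' @param prevalence marginal case probability, in (0, 0.5).
#' @param config a [simulationConfig()]; `group_sizes` entries `t1d`,
#'   `relative1`, `relative2`, `control` are honoured.
#' @param ageModel log-normal age-at-diagnosis model for cases.
#' @param panel SNP panel, default [defaultPanel()].
#' @return A [GrsCohort-class].
#' @examples
#' coh <- simulateLiabilityFamily(
#'   defaultGroupModels("CAU")$control, defaultWeights(), 0.2,
#'   simulationConfig(c(t1d = 20, control = 20), seed = 7))
#' @export
simulateLiabilityFamily <- function(populationModel, weights, prevalence,
                                    config,
                                    ageModel = list(geometric_mean = 8.94,
                                                    geometric_sd = 2.18),
                                    panel = defaultPanel()) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (prevalence <= 0 || prevalence >= 0.5)
    stop("prevalence must lie in (0, 0.5)")
  set.seed(config$seed)
  loci <- .lia_loci(populationModel, weights)
  want <- function(g) {
    v <- config$group_sizes
    if (!g %in% names(v) || is.na(v[[g]])) 0L else as.integer(v[[g]])
  }
  n_case <- want("t1d"); n_rel1 <- want("relative1")
  n_rel2 <- want("relative2"); n_ctrl <- want("control")

  # calibrate alpha on a genotype pool
  n_pool <- 20000L
  sex_pool <- ifelse(runif(n_pool) < config$sex_ratio, "male", "female")
  pool <- .lia_draw(loci, n_pool, sex_pool)
  num_pool <- .lia_numerator(pool, sex_pool, loci, weights)
  f <- function(alpha) mean(plogis(alpha + num_pool)) - prevalence
  if (f(50) < -0.02 * prevalence || f(-50) > 0.02 * prevalence)
    stop("prevalence ", prevalence,
         " unattainable for this weight configuration")
  alpha <- uniroot(f, c(-50, 50), tol = 1e-8)$root

  # accept cases by thinning simulated children; keep their parents
  acc <- list(); n_acc <- 0L
  parents_m <- parents_f <- children <- list()
  sex_children <- character()
  while (n_acc < n_case) {
    b <- max(1000L, ceiling((n_case - n_acc) / prevalence))
    sex_m <- rep("female", b); sex_f <- rep("male", b)
    mom <- .lia_draw(loci, b, sex_m)
    dad <- .lia_draw(loci, b, sex_f)
    sex_c <- ifelse(runif(b) < config$sex_ratio, "male", "female")
    kid <- .lia_child(mom, dad, seq_len(b), seq_len(b), sex_c, loci)
    num <- .lia_numerator(kid, sex_c, loci, weights)
    take <- which(runif(b) < plogis(alpha + num))
    if (length(take)) {
      sel <- function(ind, j) list(m1 = ind$m1[, j, drop = FALSE],
                                   m2 = ind$m2[, j, drop = FALSE])
      parents_m[[length(parents_m) + 1L]] <- sel(mom, take)
      parents_f[[length(parents_f) + 1L]] <- sel(dad, take)
      children[[length(children) + 1L]] <- sel(kid, take)
      sex_children <- c(sex_children, sex_c[take])
      n_acc <- n_acc + length(take)
    }
  }
  cbind_ind <- function(lst) list(
    m1 = do.call(cbind, lapply(lst, `[[`, "m1")),
    m2 = do.call(cbind, lapply(lst, `[[`, "m2")))
  mom <- cbind_ind(parents_m); dad <- cbind_ind(parents_f)
  case <- cbind_ind(children)
  case <- list(m1 = case$m1[, seq_len(n_case), drop = FALSE],
               m2 = case$m2[, seq_len(n_case), drop = FALSE])
  sex_case <- sex_children[seq_len(n_case)]

  groups <- list()
  if (n_case > 0)
    groups$t1d <- list(ind = case, sex = sex_case)
  if (n_rel1 > 0) {  # siblings of cases (same parents, new meioses)
    j <- rep_len(seq_len(n_case), n_rel1)
    sex_s <- ifelse(runif(n_rel1) < config$sex_ratio, "male", "female")
    sib <- .lia_child(mom, dad, j, j, sex_s, loci)
    groups$relative1 <- list(ind = sib, sex = sex_s)
  }
  if (n_rel2 > 0) {  # child of a sibling and a random mate
    j <- rep_len(seq_len(n_case), n_rel2)
    sex_s <- ifelse(runif(n_rel2) < 0.5, "male", "female")
    sib <- .lia_child(mom, dad, j, j, sex_s, loci)
    sex_mate <- ifelse(sex_s == "male", "female", "male")
    mate <- .lia_draw(loci, n_rel2, sex_mate)
    sex_n <- ifelse(runif(n_rel2) < config$sex_ratio, "male", "female")
    mother_is_sib <- sex_s == "female"
    nep <- .lia_child(sib, mate, seq_len(n_rel2), seq_len(n_rel2),
                      sex_n, loci)
    # where the sib is male, swap roles so the mother is the mate
    if (any(!mother_is_sib)) {
      swap <- .lia_child(mate, sib, which(!mother_is_sib),
                         which(!mother_is_sib),
                         sex_n[!mother_is_sib], loci)
      nep$m1[, !mother_is_sib] <- swap$m1
      nep$m2[, !mother_is_sib] <- swap$m2
    }
    groups$relative2 <- list(ind = nep, sex = sex_n)
  }
  if (n_ctrl > 0) {
    sex_p <- ifelse(runif(n_ctrl) < config$sex_ratio, "male", "female")
    groups$control <- list(ind = .lia_draw(loci, n_ctrl, sex_p),
                           sex = sex_p)
  }

  parts <- lapply(names(groups), function(g) {
    gr <- groups[[g]]
    n <- length(gr$sex)
    ids <- sprintf("%s_%s_%04d", populationModel$race, g, seq_len(n))
    dosage <- .lia_to_dosage(.lia_fix_x(gr$ind, gr$sex, loci), ids, panel)
    age_dx <- if (g == "t1d" && !is.null(ageModel))
      rlnorm(n, log(ageModel$geometric_mean), log(ageModel$geometric_sd))
    else rep(NA_real_, n)
    meta <- data.frame(
      sample_id = ids, group = g, sex = gr$sex,
      race = populationModel$race, ethnicity = "non_hispanic",
      age_at_diagnosis = age_dx,
      age_at_donation = runif(n, config$donation_age_range[1],
                              config$donation_age_range[2]),
      aab_count = if (g == "t1d") 2 else rbinom(n, 1,
                                                config$p_aab_relative),
      stringsAsFactors = FALSE)
    list(dosage = dosage, meta = meta)
  })
  dosage <- do.call(cbind, lapply(parts, `[[`, "dosage"))
  meta <- do.call(rbind, lapply(parts, `[[`, "meta"))
  GrsCohort(dosage, panel = panel, metadata = meta)
}

# males carry the maternal allele in both X slots so allele sums give 0/2
.lia_fix_x <- function(ind, sex, loci) {
  xrow <- c(FALSE, loci$on_x)
  male <- sex == "male"
  if (any(xrow) && any(male))
    ind$m2[xrow, male] <- ind$m1[xrow, male]
  ind
}
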