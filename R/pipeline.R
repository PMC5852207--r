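# Orchestration: QC -> HLA calls -> scoring -> statistics -> report.

.AGE_BIN_LABELS <- c("lt8", "8to16", "ge16")

.age_bin <- function(age) {
  cut(age, breaks = c(-Inf, 8, 16, Inf), right = FALSE,
      labels = .AGE_BIN_LABELS)
}

#' Run the full analysis on a cohort
#'
#' Executes the stages in order - QC, HLA imputation, scoring, group
#' summaries, discrimination (ROC + balanced-accuracy scan) per contrast,
#' the diplotype-by-age contingency block, the per-locus odds-ratio block,
#' and the age-at-diagnosis association - and returns them as one report.
#' Stage boundaries are logged with counts (no silent drops).  Contrasts
#' whose groups are absent after filtering are skipped with a warning,
#' not an error.
#'
#' @param cohort a [GrsCohort-class] (or path to a wide genotype TSV, in
#'   which case `metadata` must be supplied to [readGenotypes()] first).
#' @param weights a [GrsWeights-class], default [defaultWeights()].
#' @param race,ethnicity optional filters on the metadata labels.
#' @param contrasts list of `c(case_group, control_group)` pairs for
#'   ROC/threshold analysis.
#' @param verbose log stage counts, default `TRUE`.
#' @return list of class `"AnalysisReport"` with elements `qc`,
#'   `scores`, `group_summaries`, `roc`, `scans`, `table1`, `table2`,
#'   `age_assoc`, `outliers`, `group_comparison`.
#' @examples
#' coh <- simulateCohort(defaultGroupModels("CAU"),
#'                       simulationConfig(c(t1d = 60, control = 60),
#'                                        seed = 3))
#' rep <- runAnalysis(coh, contrasts = list(c("t1d", "control")),
#'                    verbose = FALSE)
#' rep$roc[["t1d_vs_control"]]$auc
#' @export
runAnalysis <- function(cohort, weights = defaultWeights(),
                        race = NULL, ethnicity = NULL,
                        contrasts = list(c("t1d", "control"),
                                         c("t1d", "relative1")),
                        verbose = TRUE) {
  log_ <- function(...) if (verbose) message(...)
  meta0 <- sampleData(cohort)
  keep <- rep(TRUE, ncol(cohort))
  if (!is.null(race)) keep <- keep & meta0$race %in% race
  if (!is.null(ethnicity)) keep <- keep & meta0$ethnicity %in% ethnicity
  cohort <- cohort[, keep]
  log_("input: ", ncol(cohort), " samples after stratum filtering")
  cohort <- applyQC(cohort)
  qc <- qcReport(cohort)
  log_("qc: ", qc@nRetained, " retained (",
       qc@nExcludedMissingHla, " missing HLA, ",
       qc@nExcludedLowCall, " low call)")
  meta <- sampleData(cohort)
  if (length(unique(meta$group[!is.na(meta$group)])) < 1)
    stop("no groups present after filtering")
  scores <- scoreCohort(cohort, weights)
  scores$group <- meta$group
  scores$age_at_diagnosis <- meta$age_at_diagnosis
  log_("scored: ", nrow(scores), " samples")

  by_group <- split(scores$grs, scores$group)
  group_summaries <- lapply(by_group, function(g)
    list(n = length(g), mean = mean(g), sd = sd(g),
         centiles = scoreCentiles(g)$centiles))

  roc <- list(); scans <- list()
  for (ct in contrasts) {
    nm <- paste0(ct[1], "_vs_", ct[2])
    sub <- scores[scores$group %in% ct, ]
    if (!all(ct %in% sub$group)) {
      warning("skipping contrast ", nm, ": group(s) absent")
      next
    }
    lab <- sub$group == ct[1]
    roc[[nm]] <- rocAuc(sub$grs, lab)
    scans[[nm]] <- balancedAccuracyScan(sub$grs, lab)
  }

  t1d <- scores[scores$group %in% "t1d", ]
  table1 <- if (nrow(t1d) && any(!is.na(t1d$age_at_diagnosis)))
    buildTable1(t1d$diplotype, t1d$age_at_diagnosis) else NULL
  table2 <- tryCatch(buildTable2(cohort), warning = function(w) NULL,
                     error = function(e) NULL)
  age_assoc <- if (sum(!is.na(t1d$age_at_diagnosis)) >= 3)
    ageAssociation(t1d) else NULL
  outliers <- if (!is.null(age_assoc))
    age_assoc$full$outlier_ids else character()

  comparison <- if (length(by_group) >= 2)
    rankGroupComparison(by_group) else NULL

  structure(list(qc = qc, scores = scores,
                 group_summaries = group_summaries,
                 roc = roc, scans = scans,
                 table1 = table1, table2 = table2,
                 age_assoc = age_assoc, outliers = outliers,
                 group_comparison = comparison),
            class = "AnalysisReport")
}

#' Diplotype by age-at-diagnosis contingency block
#'
#' Builds the 3 x 6 count grid of age bins (under 8, 8 to under 16, 16
#' and over) by diplotype category, and for every cell the odds ratio of
#' \{this diplotype vs all others\} x \{this age bin vs all other bins\}
#' with its Fisher's exact p-value and significance mark (dagger for
#' p < 0.05, double dagger for p < 0.01).
#'
#' @param diplotype either a vector of per-patient diplotype categories
#'   (with `age` supplied), or a ready-made 3 x 6 count matrix in the
#'   layout of [table1Reference()].
#' @param age per-patient ages at diagnosis (years); ignored when a count
#'   matrix is supplied.
#' @return list: `counts` (3 x 6 matrix), `or`, `p_value` (same shape),
#'   `mark` (character matrix, "", "+" for p<0.05, "++" for p<0.01).
#' @examples
#' tab <- buildTable1(table1Reference())
#' round(tab$or["lt8", "DR3_DR4"], 2)  # 1.97
#' @export
buildTable1 <- function(diplotype, age = NULL) {
  counts <- if (is.matrix(diplotype)) {
    stopifnot(nrow(diplotype) == 3)
    diplotype
  } else {
    ok <- !is.na(diplotype) & !is.na(age)
    table(.age_bin(age[ok]),
          factor(as.character(diplotype[ok]), levels = .DIPLOTYPE_LEVELS))
  }
  counts <- as.matrix(unclass(counts))
  or <- p <- matrix(NA_real_, nrow(counts), ncol(counts),
                    dimnames = dimnames(counts))
  for (i in seq_len(nrow(counts))) for (j in seq_len(ncol(counts))) {
    a <- counts[i, j]
    b <- sum(counts[, j]) - a
    c_ <- sum(counts[i, ]) - a
    d <- sum(counts) - a - b - c_
    est <- oddsRatioFromCounts(a, b, c_, d)
    or[i, j] <- est$odds_ratio
    p[i, j] <- est$p_value
  }
  mark <- ifelse(p < 0.01, "++", ifelse(p < 0.05, "+", ""))
  list(counts = counts, or = or, p_value = p, mark = mark)
}

#' Per-locus case-control frequency and odds-ratio block
#'
#' For every locus: the risk-allele (SNP and haplotype rows, allele-level)
#' or category (diplotype rows, subject-level) frequency among cases and
#' controls, the frequency-ratio odds ratio, its Woolf confidence
#' interval and Fisher's exact p-value from the underlying counts.
#' Computed per race stratum; strata lacking cases or controls are
#' skipped with a warning.
#'
#' @param cohort a QC'd [GrsCohort-class] whose metadata assigns `group`
#'   (uses `t1d` vs `control`) and `race`.
#' @param weights a [GrsWeights-class] (for the tag-SNP map).
#' @param races strata to compute; default: all races present.
#' @return named list (one per stratum) of `data.frame`s with columns
#'   `marker`, `kind`, `freq_t1d`, `freq_control`, `odds_ratio`,
#'   `ci_low`, `ci_high`, `p_value`.
#' @export
buildTable2 <- function(cohort, weights = defaultWeights(), races = NULL) {
  meta <- sampleData(cohort)
  if (is.null(races)) races <- unique(meta$race[!is.na(meta$race)])
  hla <- hlaCalls(cohort, weights)
  hap <- imputeHaplotypes(dosages(cohort)[weights@tagSnps[["dq6"]], ],
                          dosages(cohort)[weights@tagSnps[["a24"]], ],
                          dosages(cohort)[weights@tagSnps[["b57"]], ])
  out <- list()
  for (r in races) {
    in_r <- !is.na(meta$race) & meta$race == r
    case <- in_r & meta$group %in% "t1d"
    ctrl <- in_r & meta$group %in% "control"
    if (!any(case) || !any(ctrl)) {
      warning("stratum ", r, " lacks cases or controls; skipped")
      next
    }
    rows <- list()
    for (cat in .DIPLOTYPE_LEVELS) {       # subject-level
      p1 <- mean(hla$category[case] == cat)
      p0 <- mean(hla$category[ctrl] == cat)
      est <- oddsRatioFromFreqs(p1, p0, sum(case), sum(ctrl))
      rows[[cat]] <- data.frame(marker = cat, kind = "diplotype",
                                freq_t1d = p1, freq_control = p0, est)
    }
    for (h in .HAPLOTYPE_LEVELS) {         # allele-level, risk-oriented
      p1 <- mean(hap[[h]][case]) / 2
      p0 <- mean(hap[[h]][ctrl]) / 2
      est <- oddsRatioFromFreqs(p1, p0, 2 * sum(case), 2 * sum(ctrl))
      rows[[h]] <- data.frame(marker = h, kind = "haplotype",
                              freq_t1d = p1, freq_control = p0, est)
    }
    d <- dosages(cohort)
    for (s in names(weights@snpBeta)) {    # allele-level
      p1 <- mean(d[s, case], na.rm = TRUE) / 2
      p0 <- mean(d[s, ctrl], na.rm = TRUE) / 2
      n1 <- 2 * sum(!is.na(d[s, case])); n0 <- 2 * sum(!is.na(d[s, ctrl]))
      est <- oddsRatioFromFreqs(p1, p0, n1, n0)
      rows[[s]] <- data.frame(marker = s, kind = "snp",
                              freq_t1d = p1, freq_control = p0, est)
    }
    out[[r]] <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  }
  out
}

#' Age-at-diagnosis association of the score and its components
#'
#' Regresses the full, HLA-only and non-HLA-only scores on age at
#' diagnosis ([regressionWithBand()], 99% prediction band) and summarises
#' each score within the three age bins.
#'
#' @param scored `data.frame` from [scoreCohort()] with an
#'   `age_at_diagnosis` column (patients only).
#' @param band_level prediction-band level, default 0.99.
#' @return list: `full`, `hla_only`, `nonhla_only` (each a
#'   [regressionWithBand()] fit) and `bin_summary` (mean score per age
#'   bin per component).
#' @export
ageAssociation <- function(scored, band_level = 0.99) {
  ok <- !is.na(scored$age_at_diagnosis)
  x <- scored$age_at_diagnosis[ok]
  fits <- lapply(c(full = "grs", hla_only = "grs_hla_only",
                   nonhla_only = "grs_nonhla_only"),
                 function(col) {
                   y <- scored[[col]][ok]
                   names(y) <- scored$sample_id[ok]
                   regressionWithBand(x, y, band_level)
                 })
  bin <- .age_bin(x)
  bin_summary <- sapply(c("grs", "grs_hla_only", "grs_nonhla_only"),
                        function(col)
                          tapply(scored[[col]][ok], bin, mean))
  c(fits, list(bin_summary = bin_summary))
}

#' Serialise an analysis report to JSON
#'
#' Writes the score-free summary blocks (QC counts, group summaries, AUC,
#' peak thresholds and accuracies, contingency and locus tables,
#' age-association coefficients, outlier ids) as JSON.
#'
#' @param report an `"AnalysisReport"` from [runAnalysis()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeReport <- function(report, path) {
  qc <- report$qc
  js <- list(
    schema = "t1dgrs-report/1",
    qc = list(n_input = qc@nInput, n_retained = qc@nRetained,
              n_excluded_missing_hla = qc@nExcludedMissingHla,
              n_excluded_low_call = qc@nExcludedLowCall),
    group_summaries = report$group_summaries,
    roc = lapply(report$roc, function(r)
      list(auc = r$auc, n_case = r$n_case, n_control = r$n_control)),
    scans = lapply(report$scans, function(s)
      list(peak_threshold = s$peak_threshold,
           peak_accuracy = s$peak_accuracy,
           sens_at_peak = s$sens_at_peak, spec_at_peak = s$spec_at_peak)),
    table1 = report$table1,
    table2 = report$table2,
    age_assoc = if (!is.null(report$age_assoc))
      lapply(report$age_assoc[c("full", "hla_only", "nonhla_only")],
             function(f) list(slope = f$slope, intercept = f$intercept,
                              pearson_r = f$pearson_r,
                              p_value = f$p_value)),
    outliers = report$outliers)
  jsonlite::write_json(js, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
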