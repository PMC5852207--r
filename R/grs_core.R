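# The log-additive genetic risk score:
#
#   GRS = ( sum_i beta_i * s_i  +  H_l ) / ((n + 1) * 2)
#
# where beta_i = ln OR of locus i, s_i its risk-allele dosage, H_l the
# ln OR of the sample's HLA diplotype category, and n the number of
# beta-weighted loci tested (the "+1" is the diplotype term, each locus
# contributing two allele slots).  The beta-weighted loci are the non-HLA
# SNPs plus the three risk-oriented HLA haplotype loci (non-DQ6, A24,
# non-B57); H_l sits outside the summation.

#' Effective dosage under the hemizygous dominant-risk rule
#'
#' X-chromosome dosages in males are counted as 0 or 2 (a heterozygous
#' call, which should not occur for a true hemizygote but can arise from
#' assay noise, is promoted to 2), assuming a dominant risk effect in the
#' hemizygous state.  Autosomal loci and female samples pass through
#' unchanged, as do samples of unknown sex (with a warning, since the
#' X rule cannot be applied).
#'
#' @param dosage integer vector of dosages in \{0, 1, 2\} (may be `NA`).
#' @param chromosome chromosome labels, same length or length 1; `"X"`
#'   marks X-linked loci.
#' @param sex `"male"`, `"female"` or `"unknown"` (scalar).
#' @return numeric vector of effective dosages.
#' @examples
#' effectiveDosage(c(0, 1, 2), "X", "male")
#' @export
effectiveDosage <- function(dosage, chromosome, sex = "unknown") {
  stopifnot(length(sex) == 1)
  on_x <- chromosome == "X"
  if (!any(on_x, na.rm = TRUE)) return(dosage)
  if (is.na(sex) || sex == "unknown") {
    warning("sex unknown; X-chromosome dosages left unadjusted")
    return(dosage)
  }
  if (sex == "male") {
    adj <- dosage
    adj[on_x & !is.na(dosage) & dosage >= 1] <- 2
    return(adj)
  }
  dosage
}

#' Compute the genetic risk score for one sample
#'
#' The numerator sums `beta * effective dosage` over the called
#' beta-weighted loci (non-HLA SNPs in panel order, then the three
#' haplotype loci) and adds the diplotype weight H.  The denominator is
#' `(n + 1) * 2`, where `n` counts the called beta-weighted loci for this
#' sample (`missingPolicy = "per_sample_n"`, the default) or the full
#' configured panel (`"panel_n"`).  The HLA-only and non-HLA-only
#' component scores share the full score's denominator, so the three
#' scores are directly comparable and their numerators add exactly.
#'
#' @param snp_dosages named numeric vector of non-HLA risk-allele dosages
#'   (`NA` = missing call).
#' @param hla one row of [hlaCalls()] output (or any list with elements
#'   `category`, `non_dq6`, `a24`, `non_b57`).
#' @param weights a [GrsWeights-class].
#' @param sex sample sex, for the X-chromosome rule.
#' @param missingPolicy `"per_sample_n"` or `"panel_n"`.
#' @return one-row `data.frame`: `grs`, `grs_hla_only`, `grs_nonhla_only`,
#'   `n_used`, `numerator`.
#' @examples
#' w <- defaultWeights()
#' dos <- setNames(rep(1, length(w@snpBeta)), names(w@snpBeta))
#' computeGrs(dos, list(category = "X_X", non_dq6 = 2, a24 = 1,
#'                      non_b57 = 2), w)
#' @export
computeGrs <- function(snp_dosages, hla, weights,
                       sex = "unknown",
                       missingPolicy = c("per_sample_n", "panel_n")) {
  missingPolicy <- match.arg(missingPolicy)
  beta <- weights@snpBeta
  called <- names(snp_dosages)[!is.na(snp_dosages)]
  unweighted <- setdiff(called, names(beta))
  if (length(unweighted))
    stop("no weight configured for called SNP(s): ",
         paste(unweighted, collapse = ", "))
  s <- snp_dosages[names(beta)]                    # panel order
  chrom <- weights@chromosome[names(beta)]
  s_eff <- effectiveDosage(s, chrom, sex)
  used <- !is.na(s_eff)
  num_nonhla <- sum(beta[used] * s_eff[used])
  hb <- weights@haplotypeBeta
  hap_dos <- c(non_dq6 = as.numeric(hla$non_dq6), a24 = as.numeric(hla$a24),
               non_b57 = as.numeric(hla$non_b57))[names(hb)]
  H <- weights@diplotypeBeta[[as.character(hla$category)]]
  num_hla <- sum(hb * hap_dos) + H
  n_used <- sum(used) + length(hb)
  n <- if (missingPolicy == "per_sample_n") n_used else nPanel(weights)
  denom <- (n + 1) * 2
  data.frame(grs = (num_nonhla + num_hla) / denom,
             grs_hla_only = num_hla / denom,
             grs_nonhla_only = num_nonhla / denom,
             n_used = n_used,
             numerator = num_nonhla + num_hla)
}

#' Score every sample in a cohort
#'
#' Vectorised cohort scoring: HLA calls via [hlaCalls()], then the score
#' of [computeGrs()] per sample.  Deterministic given its inputs and
#' invariant to sample order.
#'
#' @param cohort a QC'd [GrsCohort-class].
#' @param weights a [GrsWeights-class].
#' @param missingPolicy see [computeGrs()].
#' @return `data.frame` with one row per sample: `sample_id`, `grs`,
#'   `grs_hla_only`, `grs_nonhla_only`, `n_used`, `diplotype`,
#'   `conflict_flag`.
#' @examples
#' coh <- simulateCohort(defaultGroupModels("CAU"),
#'                       simulationConfig(c(t1d = 3, control = 3), seed = 1))
#' scoreCohort(coh, defaultWeights())
#' @export
scoreCohort <- function(cohort, weights,
                        missingPolicy = c("per_sample_n", "panel_n")) {
  missingPolicy <- match.arg(missingPolicy)
  hla <- hlaCalls(cohort, weights)
  d <- dosages(cohort)
  sexes <- colData(cohort)$sex
  if (is.null(sexes)) sexes <- rep("unknown", ncol(d))
  sexes[is.na(sexes)] <- "unknown"
  snp_ids <- names(weights@snpBeta)
  absent <- setdiff(snp_ids, rownames(d))
  if (length(absent))
    stop("weighted SNPs absent from cohort panel: ",
         paste(absent, collapse = ", "))
  rows <- lapply(seq_len(ncol(d)), function(j) {
    res <- tryCatch(
      computeGrs(d[snp_ids, j], hla[j, ], weights,
                 sex = sexes[j], missingPolicy = missingPolicy),
      error = function(e) stop("sample ", colnames(d)[j], ": ",
                               conditionMessage(e), call. = FALSE))
    res
  })
  out <- do.call(rbind, rows)
  data.frame(sample_id = colnames(d),
             out[, c("grs", "grs_hla_only", "grs_nonhla_only", "n_used")],
             diplotype = as.character(hla$category),
             conflict_flag = hla$conflict,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Attainable score bounds under a weight configuration
#'
#' The extreme scores reachable by pushing every locus to its extreme
#' dosage (0 for positive weights, 2 for negative ones, and vice versa)
#' and taking the least/greatest diplotype weight, under the `panel_n`
#' denominator.  Every score of a fully called sample must lie inside.
#'
#' @param weights a [GrsWeights-class].
#' @return named numeric `c(min, max)`.
#' @export
grsBounds <- function(weights) {
  b <- c(weights@snpBeta, weights@haplotypeBeta)
  denom <- (nPanel(weights) + 1) * 2
  lo <- (sum(2 * pmin(b, 0)) + min(weights@diplotypeBeta)) / denom
  hi <- (sum(2 * pmax(b, 0)) + max(weights@diplotypeBeta)) / denom
  c(min = lo, max = hi)
}

#' Write scored-cohort output
#' @param scores `data.frame` from [scoreCohort()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
writeScores <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
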