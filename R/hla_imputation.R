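# Tag-SNP imputation of the HLA-DR3-DQ2/DR4-DQ8 diplotype categories and
# the DR15-DQ6 / A24 / B57 haplotype dosages.

#' Impute the six-category HLA diplotype from tag-SNP dosages
#'
#' Maps the DR3-DQ2 tag dosage (rs2187668 by default) and the DR4-DQ8 tag
#' dosage (rs7454108) to one of the six diplotype categories: two
#' haplotypes are available, so the tags determine the category directly.
#' A combined dosage above 2 is impossible on two haplotypes; such
#' combinations ((2,1), (1,2), (2,2)) are assigned the highest-risk
#' compatible category, `DR3_DR4`, and flagged as conflicts rather than
#' dropped, so that they stay analyzable and surface in reports.
#'
#' @param dr3,dr4 integer dosages in \{0, 1, 2\} of the DR3-DQ2 and
#'   DR4-DQ8 tag alleles; vectorised, must be non-missing (guaranteed
#'   after [applyQC()]).
#' @return `data.frame` with columns `category` (factor over the six
#'   levels) and `conflict` (logical).
#' @examples
#' imputeDiplotype(c(1, 0, 2), c(1, 0, 1))
#' @export
imputeDiplotype <- function(dr3, dr4) {
  if (length(dr3) != length(dr4))
    stop("dr3 and dr4 dosages must have equal length")
  if (anyNA(dr3) || anyNA(dr4))
    stop("missing tag dosage; samples lacking HLA calls must be excluded by QC")
  if (!all(dr3 %in% 0:2 & dr4 %in% 0:2))
    stop("tag dosages must be 0, 1 or 2")
  conflict <- dr3 + dr4 > 2
  category <- character(length(dr3))
  category[conflict] <- "DR3_DR4"
  ok <- !conflict
  category[ok & dr3 >= 1 & dr4 >= 1] <- "DR3_DR4"
  category[ok & dr3 == 2 & dr4 == 0] <- "DR3_DR3"
  category[ok & dr3 == 0 & dr4 == 2] <- "DR4_DR4"
  category[ok & dr3 == 1 & dr4 == 0] <- "DR3_X"
  category[ok & dr3 == 0 & dr4 == 1] <- "DR4_X"
  category[ok & dr3 == 0 & dr4 == 0] <- "X_X"
  data.frame(category = factor(category, levels = .DIPLOTYPE_LEVELS),
             conflict = conflict)
}

#' Orient haplotype tag dosages to risk
#'
#' DR15-DQ6 and B57 are protective, so their risk-oriented dosages are the
#' complements (2 - dosage): the count of non-DR15-DQ6 and non-B57
#' haplotypes.  A24 is already in risk orientation and passes through.
#' The re-orientation happens here, once, so the scoring code only ever
#' sees risk-oriented dosages.
#'
#' @param dq6,a24,b57 integer dosages in \{0, 1, 2\} of the DQ6, A24 and
#'   B57 tag alleles (haplotype orientation); vectorised, non-missing.
#' @return `data.frame` with columns `non_dq6`, `a24`, `non_b57`.
#' @examples
#' imputeHaplotypes(dq6 = 0:2, a24 = c(1, 1, 1), b57 = c(2, 1, 0))
#' @export
imputeHaplotypes <- function(dq6, a24, b57) {
  for (d in list(dq6, a24, b57)) {
    if (anyNA(d)) stop("missing haplotype tag dosage")
    if (!all(d %in% 0:2)) stop("tag dosages must be 0, 1 or 2")
  }
  data.frame(non_dq6 = 2 - dq6, a24 = a24, non_b57 = 2 - b57)
}

#' HLA calls for every sample in a cohort
#'
#' Runs [imputeDiplotype()] and [imputeHaplotypes()] across a cohort,
#' locating the tag SNPs through the weight configuration's tag map
#' (array dialects differ, so the tag identities are configuration, not
#' code).
#'
#' @param cohort a QC'd [GrsCohort-class].
#' @param weights a [GrsWeights-class] supplying the tag-SNP map.
#' @return `data.frame` with columns `sample_id`, `category`, `conflict`,
#'   `non_dq6`, `a24`, `non_b57`.
#' @export
hlaCalls <- function(cohort, weights) {
  d <- dosages(cohort)
  tags <- weights@tagSnps
  absent <- setdiff(tags, rownames(d))
  if (length(absent))
    stop("tag SNPs absent from cohort panel: ",
         paste(absent, collapse = ", "))
  dip <- imputeDiplotype(d[tags[["dr3"]], ], d[tags[["dr4"]], ])
  hap <- imputeHaplotypes(d[tags[["dq6"]], ], d[tags[["a24"]], ],
                          d[tags[["b57"]], ])
  data.frame(sample_id = colnames(d), dip, hap,
             stringsAsFactors = FALSE, row.names = NULL)
}
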