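#' GrsCohort: dosage matrix plus panel and subject metadata
#'
#' A \linkS4class{SummarizedExperiment} specialised for risk-allele dosage
#' data.  The single assay `"dosage"` is a SNP-by-sample matrix with values
#' in \{0, 1, 2, `NA`\} counting risk alleles (orientation to the risk
#' allele happens at read time).  `rowData` carries the SNP panel
#' (see [defaultPanel()]); `colData` the subject metadata: `group`
#' (control, relative2, relative1, at_risk, t1d), `sex`, `race`,
#' `ethnicity`, `age_at_diagnosis`, `age_at_donation` and `aab_count`.
#' Metadata fields may be `NA`; they are never fabricated.
#'
#' @slot ... inherited from \linkS4class{SummarizedExperiment}.
#' @seealso [GrsCohort()] for construction, [applyQC()], [scoreCohort()].
#' @aliases GrsCohort-class
#' @exportClass GrsCohort
setClass("GrsCohort", contains = "SummarizedExperiment")

setValidity("GrsCohort", function(object) {
  msg <- NULL
  if (!"dosage" %in% assayNames(object))
    msg <- c(msg, "assay 'dosage' is required")
  else {
    d <- assay(object, "dosage")
    bad <- !(is.na(d) | d %in% c(0, 1, 2))
    if (any(bad))
      msg <- c(msg, "dosage values must be 0, 1, 2 or NA")
  }
  need <- c("snp_id", "risk_allele", "chromosome", "is_hla_tag", "role")
  if (!all(need %in% colnames(rowData(object))))
    msg <- c(msg, paste("rowData must contain:",
                        paste(need, collapse = ", ")))
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample identifiers must be unique")
  if (anyDuplicated(rowData(object)$snp_id))
    msg <- c(msg, "snp_id must be unique within the panel")
  if (is.null(msg)) TRUE else msg
})

#' Construct a GrsCohort
#'
#' @param dosage numeric matrix of risk-allele dosages, SNPs in rows and
#'   samples in columns; values 0/1/2 or `NA`.  Row names must match
#'   `panel$snp_id`, column names are sample identifiers.
#' @param panel `data.frame` of SNP definitions as from [defaultPanel()].
#' @param metadata optional `data.frame` of per-sample metadata with a
#'   `sample_id` column (a sidecar table); matched to columns of `dosage`
#'   by `sample_id`, missing fields become `NA`.
#' @return A [GrsCohort-class] object.
#' @examples
#' pan <- defaultPanel()
#' dos <- matrix(0L, nrow(pan), 2,
#'               dimnames = list(pan$snp_id, c("s1", "s2")))
#' GrsCohort(dos, pan)
#' @export
GrsCohort <- function(dosage, panel = defaultPanel(), metadata = NULL) {
  if (is.null(rownames(dosage)))
    stop("dosage matrix must have SNP row names")
  if (is.null(colnames(dosage)))
    stop("dosage matrix must have sample column names")
  unknown <- setdiff(rownames(dosage), panel$snp_id)
  if (length(unknown))
    stop("dosage rows absent from the panel: ",
         paste(unknown, collapse = ", "))
  panel <- panel[match(rownames(dosage), panel$snp_id), , drop = FALSE]
  cd <- .align_metadata(colnames(dosage), metadata)
  new("GrsCohort", SummarizedExperiment(
    assays = list(dosage = dosage),
    rowData = S4Vectors::DataFrame(panel, row.names = panel$snp_id),
    colData = cd))
}

.META_COLS <- c("group", "sex", "race", "ethnicity", "age_at_diagnosis",
                "age_at_donation", "aab_count")

.align_metadata <- function(sample_ids, metadata) {
  cd <- S4Vectors::DataFrame(row.names = sample_ids)
  for (col in .META_COLS)
    cd[[col]] <- if (col %in% c("age_at_diagnosis", "age_at_donation",
                                "aab_count")) NA_real_ else NA_character_
  if (!is.null(metadata)) {
    if (!"sample_id" %in% colnames(metadata))
      stop("metadata must have a sample_id column")
    i <- match(sample_ids, metadata$sample_id)
    for (col in intersect(.META_COLS, colnames(metadata)))
      cd[[col]] <- metadata[[col]][i]
  }
  cd
}

#' QcReport: partition of samples by quality-control outcome
#'
#' Records the outcome of [applyQC()]: samples missing any HLA tag-SNP
#' call are excluded under the HLA rule; of the remainder, samples with a
#' called fraction of non-HLA panel SNPs below the threshold are excluded
#' under the low-call rule.  A sample failing both rules is counted once,
#' under the HLA rule, so the three counts always partition the input.
#'
#' @slot nInput,nRetained,nExcludedMissingHla,nExcludedLowCall integer counts.
#' @slot excludedIds character vector of excluded sample identifiers.
#' @exportClass QcReport
setClass("QcReport", representation(
  nInput = "integer", nRetained = "integer",
  nExcludedMissingHla = "integer", nExcludedLowCall = "integer",
  excludedIds = "character"))

setValidity("QcReport", function(object) {
  if (object@nInput != object@nRetained + object@nExcludedMissingHla +
      object@nExcludedLowCall)
    return("QC counts do not partition nInput")
  TRUE
})

#' @describeIn QcReport-class compact display.
#' @param object a `QcReport`.
#' @export
setMethod("show", "QcReport", function(object) {
  cat("QcReport:", object@nInput, "samples in,",
      object@nRetained, "retained\n",
      " excluded - missing HLA call:", object@nExcludedMissingHla,
      "; low non-HLA call rate:", object@nExcludedLowCall, "\n")
})

#' GrsWeights: log-odds weights for the genetic risk score
#'
#' Holds the per-SNP weights (beta = ln OR), the HLA diplotype weight
#' lookup H over the six categories, the three haplotype weights
#' (non-DQ6, A24, non-B57, risk orientation) and the tag-SNP map that
#' identifies which panel SNPs tag which HLA haplotype.  Built by
#' [readWeights()] from a JSON configuration of odds ratios; weights are
#' data, not code.
#'
#' @slot snpBeta named numeric, ln odds ratio per non-HLA SNP.
#' @slot diplotypeBeta named numeric over the six diplotype categories.
#' @slot haplotypeBeta named numeric over `non_dq6`, `a24`, `non_b57`.
#' @slot tagSnps named character mapping `dr3`, `dr4`, `dq6`, `a24`, `b57`
#'   to panel SNP identifiers.
#' @slot riskAllele,chromosome named character, per non-HLA SNP (the
#'   chromosome label flags X-linked loci for the hemizygous dosage rule).
#' @seealso [readWeights()], [defaultWeights()], [computeGrs()].
#' @exportClass GrsWeights
setClass("GrsWeights", representation(
  snpBeta = "numeric", diplotypeBeta = "numeric", haplotypeBeta = "numeric",
  tagSnps = "character", riskAllele = "character", chromosome = "character"))

setValidity("GrsWeights", function(object) {
  msg <- NULL
  if (!all(is.finite(object@snpBeta)))
    msg <- c(msg, "all SNP weights must be finite")
  if (!setequal(names(object@diplotypeBeta), .DIPLOTYPE_LEVELS))
    msg <- c(msg, paste("diplotype weights must cover exactly:",
                        paste(.DIPLOTYPE_LEVELS, collapse = ", ")))
  if (length(object@haplotypeBeta) &&
      !setequal(names(object@haplotypeBeta), .HAPLOTYPE_LEVELS))
    msg <- c(msg, "haplotype weights must cover non_dq6, a24, non_b57 (or be absent)")
  if (!all(c("dr3", "dr4", "dq6", "a24", "b57") %in% names(object@tagSnps)))
    msg <- c(msg, "tagSnps must name dr3, dr4, dq6, a24 and b57 tags")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn GrsWeights-class compact display.
#' @param object a `GrsWeights`.
#' @export
setMethod("show", "GrsWeights", function(object) {
  cat("GrsWeights:", length(object@snpBeta), "SNP weights,",
      length(object@haplotypeBeta), "haplotype weights,",
      length(object@diplotypeBeta), "diplotype categories\n",
      " beta-weighted loci (n_panel):", nPanel(object), "\n")
})
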