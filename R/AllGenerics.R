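#' @name t1dgrs-generics
#' @title Generics for cohort containers
#' @param x,object a [GrsCohort-class] or [GrsWeights-class] object.
#' @param ... passed to methods.
#' @keywords internal
NULL

#' Extract the dosage matrix
#' @param x a [GrsCohort-class].
#' @return numeric matrix, SNPs by samples.
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname dosages
#' @export
setMethod("dosages", "GrsCohort", function(x) assay(x, "dosage"))

#' Extract the SNP panel
#' @param x a [GrsCohort-class].
#' @return `data.frame` of SNP definitions.
#' @export
setGeneric("snpPanel", function(x) standardGeneric("snpPanel"))

#' @rdname snpPanel
#' @export
setMethod("snpPanel", "GrsCohort",
          function(x) as.data.frame(rowData(x)))

#' Extract per-sample metadata
#' @param x a [GrsCohort-class].
#' @return `data.frame` keyed by sample, with a `sample_id` column.
#' @export
setGeneric("sampleData", function(x) standardGeneric("sampleData"))

#' @rdname sampleData
#' @export
setMethod("sampleData", "GrsCohort", function(x) {
  df <- as.data.frame(colData(x))
  cbind(sample_id = colnames(x), df, stringsAsFactors = FALSE)
})

#' Retrieve the QC report attached by applyQC
#' @param x a [GrsCohort-class] that has been through [applyQC()].
#' @return a [QcReport-class], or `NULL` if QC has not been applied.
#' @export
setGeneric("qcReport", function(x) standardGeneric("qcReport"))

#' @rdname qcReport
#' @export
setMethod("qcReport", "GrsCohort", function(x) metadata(x)$qc)

#' Number of beta-weighted loci in a weight configuration
#'
#' The count of loci carrying their own ln-OR weight inside the score's
#' summation: the non-HLA SNPs plus the three HLA haplotype loci.  The
#' diplotype term is not counted here; it contributes the "+1" in the
#' score's denominator.
#' @param x a [GrsWeights-class].
#' @return integer.
#' @export
setGeneric("nPanel", function(x) standardGeneric("nPanel"))

#' @rdname nPanel
#' @export
setMethod("nPanel", "GrsWeights",
          function(x) length(x@snpBeta) + length(x@haplotypeBeta))
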