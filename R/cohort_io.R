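# Genotype/metadata input, sample-level QC and weight configuration.
#
# Dosage - the count of risk alleles - is the internal currency; any
# orientation to the configured risk allele happens here at read time so
# that downstream code never sees allele letters.

#' Read a genotype table into a GrsCohort
#'
#' Two input paths are supported.  `wide_tsv`: a TSV/CSV whose first
#' column is `sample_id` and remaining columns are rsIDs, with cells in
#' \{0, 1, 2, NA\} (already risk-allele dosages).  `vcf`: a VCF 4.x file
#' whose records are matched to the panel on the ID field; unphased
#' diploid genotypes are converted to risk-allele dosages, flipping
#' orientation when the panel's risk allele is the REF (or the strand
#' complement of REF/ALT).  Half-calls (`./1`) and unparseable cells
#' become missing.
#'
#' @param path path to the genotype file.
#' @param format `"wide_tsv"` (also reads comma-separated files) or `"vcf"`.
#' @param metadata optional sidecar metadata: a path to a TSV with columns
#'   `sample_id`, `group`, `race`, `ethnicity`, `sex`, `age_at_diagnosis`,
#'   `age_at_donation`, `aab_count`, or an equivalent `data.frame`.
#' @param panel SNP panel, default [defaultPanel()].  Genotype columns
#'   (or VCF records) not present in the panel are dropped with a warning.
#' @return A [GrsCohort-class].
#' @seealso [writeGenotypes()] for the inverse of the `wide_tsv` path.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' pan <- defaultPanel()
#' m <- matrix(1L, 2, nrow(pan), dimnames = list(NULL, pan$snp_id))
#' write.table(data.frame(sample_id = c("a", "b"), m, check.names = FALSE),
#'             tf, sep = "\t", quote = FALSE, row.names = FALSE)
#' readGenotypes(tf)
#' @export
readGenotypes <- function(path, format = c("wide_tsv", "vcf"),
                          metadata = NULL, panel = defaultPanel()) {
  format <- tryCatch(match.arg(format),
                     error = function(e) stop("unknown genotype format: ",
                                              format[1], call. = FALSE))
  if (!file.exists(path)) stop("no such file: ", path)
  meta <- if (is.character(metadata)) readMetadata(metadata) else metadata
  dosage <- switch(format,
                   wide_tsv = .read_wide(path, panel),
                   vcf = .read_vcf(path, panel))
  GrsCohort(dosage, panel = panel, metadata = meta)
}

.read_wide <- function(path, panel) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""), colClasses = "character")
  if (!"sample_id" %in% colnames(tab))
    stop("wide genotype table needs a sample_id column")
  ids <- tab$sample_id
  if (anyDuplicated(ids))
    stop("duplicate sample_id in genotype table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  snp_cols <- setdiff(colnames(tab), "sample_id")
  unknown <- setdiff(snp_cols, panel$snp_id)
  if (length(unknown)) {
    warning("dropping genotype columns not in the panel: ",
            paste(unknown, collapse = ", "))
    snp_cols <- setdiff(snp_cols, unknown)
  }
  m <- suppressWarnings(
    matrix(as.numeric(as.matrix(tab[, snp_cols, drop = FALSE])),
           nrow = length(ids),
           dimnames = list(ids, snp_cols)))
  m[!(m %in% c(0, 1, 2))] <- NA  # unparseable calls become missing
  t(m)
}

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

.read_vcf <- function(path, panel) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fixm <- vcfR::getFIX(v)
  if (is.null(dim(fixm))) fixm <- t(fixm)  # single-record VCF
  fix <- as.data.frame(fixm, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  keep <- fix$ID %in% panel$snp_id
  if (any(!keep))
    warning("dropping VCF records not in the panel: ",
            paste(fix$ID[!keep], collapse = ", "))
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  if (anyDuplicated(colnames(gt)))
    stop("duplicate sample_id in VCF")
  alt_count <- .gt_alt_count(gt)
  risk <- panel$risk_allele[match(fix$ID, panel$snp_id)]
  dosage <- matrix(NA_real_, nrow(gt), ncol(gt),
                   dimnames = list(fix$ID, colnames(gt)))
  for (i in seq_len(nrow(gt))) {
    orient <- .orient_risk(risk[i], fix$REF[i], fix$ALT[i], fix$ID[i])
    dosage[i, ] <- if (orient == "alt") alt_count[i, ] else 2 - alt_count[i, ]
  }
  dosage
}

# ALT-allele count per diploid unphased genotype; anything with a missing
# haploid call (including half-calls) is NA.
.gt_alt_count <- function(gt) {
  cnt <- function(g) {
    if (is.na(g)) return(NA_real_)
    al <- strsplit(g, "[/|]")[[1]]
    if (length(al) != 2 || any(al == ".")) return(NA_real_)
    sum(al == "1")
  }
  apply(gt, c(1, 2), cnt)
}

.orient_risk <- function(risk, ref, alt, id) {
  if (risk == alt) return("alt")
  if (risk == ref) return("ref")
  if (identical(.COMPLEMENT[[risk]], alt)) return("alt")
  if (identical(.COMPLEMENT[[risk]], ref)) return("ref")
  stop("risk allele ", risk, " for ", id,
       " matches neither REF/ALT (", ref, "/", alt,
       ") nor their complements")
}

#' Write a GrsCohort's dosages as a wide TSV
#'
#' Inverse of the `wide_tsv` path of [readGenotypes()]: first column
#' `sample_id`, one column per panel SNP, cells 0/1/2/NA.
#'
#' @param cohort a [GrsCohort-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGenotypes <- function(cohort, path) {
  d <- t(dosages(cohort))
  out <- data.frame(sample_id = rownames(d), d,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a metadata sidecar table
#'
#' @param path TSV with columns `sample_id`, `group`, `race`, `ethnicity`,
#'   `sex`, `age_at_diagnosis`, `age_at_donation`, `aab_count` (any subset;
#'   missing fields stay `NA`).
#' @return `data.frame`.
#' @export
readMetadata <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, na.strings = c("NA", ""))
}

#' Write a cohort's metadata sidecar
#' @param cohort a [GrsCohort-class].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
writeMetadata <- function(cohort, path) {
  utils::write.table(sampleData(cohort), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Apply sample-level quality control
#'
#' Retains samples that have every HLA tag SNP called and at least
#' `minNonHlaCallFraction` of the non-HLA panel SNPs called.  The
#' threshold is inclusive: a sample at exactly the boundary is retained
#' (exclusion applies strictly below it).  A sample failing both rules is
#' attributed to the HLA rule, making the report a deterministic
#' partition.  Applying QC twice is a no-op.
#'
#' @param cohort a [GrsCohort-class].
#' @param minNonHlaCallFraction minimum called fraction of non-HLA SNPs,
#'   default 0.9.
#' @return The filtered [GrsCohort-class]; the corresponding
#'   [QcReport-class] is attached and available via [qcReport()].
#' @examples
#' coh <- simulateCohort(defaultGroupModels("CAU"),
#'                       simulationConfig(c(control = 5), seed = 1))
#' qcReport(applyQC(coh))
#' @export
applyQC <- function(cohort, minNonHlaCallFraction = 0.9) {
  d <- dosages(cohort)
  hla <- rowData(cohort)$is_hla_tag
  n_nonhla <- sum(!hla)
  if (ncol(d) == 0) {
    rep0 <- new("QcReport", nInput = 0L, nRetained = 0L,
                nExcludedMissingHla = 0L, nExcludedLowCall = 0L,
                excludedIds = character())
    metadata(cohort)$qc <- rep0
    return(cohort)
  }
  miss_hla <- colSums(is.na(d[hla, , drop = FALSE])) > 0
  call_frac <- colSums(!is.na(d[!hla, , drop = FALSE])) / n_nonhla
  low_call <- !miss_hla & call_frac < minNonHlaCallFraction
  keep <- !miss_hla & !low_call
  rep <- new("QcReport",
             nInput = ncol(d),
             nRetained = sum(keep),
             nExcludedMissingHla = sum(miss_hla),
             nExcludedLowCall = sum(low_call),
             excludedIds = colnames(d)[!keep])
  out <- cohort[, keep]
  metadata(out)$qc <- rep
  out
}

#' Read a weight configuration
#'
#' Parses a JSON weight configuration listing per-SNP odds ratios, the
#' six-category HLA diplotype odds-ratio table, the three haplotype odds
#' ratios (non-DQ6, A24, non-B57; risk orientation) and the tag-SNP map.
#' Every odds ratio is converted to a weight beta = ln(OR).  All six
#' diplotype categories must be present and every OR strictly positive.
#'
#' @param path JSON file; see `system.file("extdata", "weights_cau.json",
#'   package = "t1dgrs")` for the shipped default.
#' @return A [GrsWeights-class].
#' @export
readWeights <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(cfg$snps) || is.null(cfg$hla_diplotype_or))
    stop("weight config needs 'snps' and 'hla_diplotype_or' entries")
  snp_or <- vapply(cfg$snps, function(s) as.numeric(s$or), numeric(1))
  names(snp_or) <- vapply(cfg$snps, function(s) s$snp_id, character(1))
  hap_or <- if (is.null(cfg$haplotype_or)) numeric(0)
            else unlist(cfg$haplotype_or)
  dip_or <- unlist(cfg$hla_diplotype_or)
  if (is.null(cfg$tag_snps))
    stop("weight config needs a 'tag_snps' map")
  ors <- c(snp_or, hap_or, dip_or)
  if (any(!is.finite(ors) | ors <= 0))
    stop("all odds ratios must be finite and > 0; offending entries: ",
         paste(names(ors)[!is.finite(ors) | ors <= 0], collapse = ", "))
  missing_cat <- setdiff(.DIPLOTYPE_LEVELS, names(dip_or))
  if (length(missing_cat))
    stop("weight config missing diplotype categories: ",
         paste(missing_cat, collapse = ", "))
  new("GrsWeights",
      snpBeta = log(snp_or),
      diplotypeBeta = log(dip_or)[.DIPLOTYPE_LEVELS],
      haplotypeBeta = if (length(hap_or)) log(hap_or)[.HAPLOTYPE_LEVELS]
                      else numeric(0),
      tagSnps = unlist(cfg$tag_snps),
      riskAllele = setNames(
        vapply(cfg$snps, function(s) s$risk_allele, character(1)),
        names(snp_or)),
      chromosome = setNames(
        vapply(cfg$snps, function(s) as.character(s$chromosome),
               character(1)),
        names(snp_or)))
}

#' Default weight configuration
#'
#' Loads the configuration shipped with the package.  Its odds ratios are
#' the published per-locus case-control values for the Caucasian cohort
#' (see [table2Reference()]); like any weight configuration they are data,
#' replaceable via [readWeights()].
#'
#' @return A [GrsWeights-class].
#' @examples
#' defaultWeights()
#' @export
defaultWeights <- function() {
  readWeights(system.file("extdata", "weights_cau.json",
                          package = "t1dgrs", mustWork = TRUE))
}
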