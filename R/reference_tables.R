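# Published reference tables used for default panels, weights and the
# synthetic-data group models. Frequencies are the printed cohort
# risk-allele (or diplotype/haplotype) frequencies; protective HLA loci
# (DR15-DQ6, B57) are expressed in risk orientation, i.e. as the
# non-DR15-DQ6 / non-B57 haplotype.

.DIPLOTYPE_LEVELS <- c("DR3_DR4", "DR4_DR4", "DR3_DR3", "DR4_X", "DR3_X", "X_X")
.HAPLOTYPE_LEVELS <- c("non_dq6", "a24", "non_b57")
.GROUP_LEVELS <- c("control", "relative2", "relative1", "at_risk", "t1d")

.panel_nonhla <- function() {
  snp <- c("rs2476601", "rs3024505", "rs1990760", "rs3087243", "rs11711054",
           "rs17388568", "rs11755527", "rs1738074", "rs1574285", "rs12722495",
           "rs2104286", "rs689", "rs2292239", "rs10877012", "rs653178",
           "rs3825932", "rs4788084", "rs7202877", "rs2290400", "rs7221109",
           "rs1893217", "rs763361", "rs2304256", "rs602662", "rs2281808",
           "rs11203203", "rs229541", "rs2664170")
  locus <- c("1p13.2", "1q32.1", "2q24.2", "2q33.2", "3p21.31", "4q27",
             "6q15", "6q25.3", "9p24.2", "10p15.1", "10p15.1", "11p15.5",
             "12q13.2", "12q14.1", "12q24.12", "15q25.1", "16p11.2",
             "16q23.1", "17q12", "17q21.2", "18p11.21", "18q22.2", "19p13.2",
             "19q13.33", "20p13", "21q22.3", "22q12.3", "Xq28")
  gene <- c("PTPN22", "IL10", "IFIH1", "CTLA4", "CCR5", "ADAD1/IL2/IL21",
            "BACH2", "TAGAP", "GLIS3", "IL2RA", "IL2RA", "INS/INS-IGF2/TH",
            "ERBB3", "CYP27B1", "ATXN2/SH2B3/NAA25", "CTSH", "NUPR1/IL27",
            "CTRB2/CTRB1", "GSDMB/ORMDL3", "CCR7/SMARCE1", "PTPN2", "CD226",
            "TYK2", "FUT2", "SIRPG/SIRPB1", "UBASH3A", "RAC2", "GAB3")
  risk <- c("A", "G", "T", "G", "A", "A", "G", "C", "G", "T", "T", "T", "T",
            "G", "C", "C", "C", "G", "C", "T", "G", "T", "C", "A", "C", "A",
            "G", "G")
  chrom <- sub("[pq].*$", "", locus)
  data.frame(snp_id = snp, locus = locus, gene = gene, risk_allele = risk,
             chromosome = chrom, is_hla_tag = FALSE,
             role = "nonhla", stringsAsFactors = FALSE)
}

.panel_hla <- function() {
  data.frame(
    snp_id = c("rs2187668", "rs7454108", "rs3129889", "rs1264813", "rs2395029"),
    locus = rep("6p21.32", 5),
    gene = c("HLA DR3-DQ2", "HLA DR4-DQ8", "HLA DR15-DQ6", "HLA A24",
             "HLA B57"),
    risk_allele = c("T", "C", "G", "A", "G"),
    chromosome = "6",
    is_hla_tag = TRUE,
    role = c("dr3_tag", "dr4_tag", "dq6_tag", "a24_tag", "b57_tag"),
    stringsAsFactors = FALSE)
}

#' Default SNP panel
#'
#' The genotyping panel behind the default configuration: five HLA tag SNPs
#' (tagging DR3-DQ2, DR4-DQ8, DR15-DQ6, A24 and B57) and 28 non-HLA
#' susceptibility SNPs.  Tag-SNP dosages for the protective DR15-DQ6 and
#' B57 haplotypes are stored in haplotype orientation and re-oriented to
#' risk by [imputeHaplotypes()].
#'
#' @return A `data.frame` with one row per SNP and columns `snp_id`,
#'   `locus` (cytoband), `gene`, `risk_allele`, `chromosome` (with `"X"`
#'   flagging X-linked loci), `is_hla_tag` and `role` (one of `dr3_tag`,
#'   `dr4_tag`, `dq6_tag`, `a24_tag`, `b57_tag`, `nonhla`).
#' @examples
#' pan <- defaultPanel()
#' table(pan$is_hla_tag)
#' @export
defaultPanel <- function() {
  rbind(.panel_hla(), .panel_nonhla())
}

#' Published per-locus case-control frequencies and odds ratios
#'
#' The published per-locus risk-allele (SNP rows), risk-haplotype
#' (DR15-DQ6/A24/B57 rows, risk orientation) and diplotype (six HLA
#' category rows, subject-level) frequencies in type 1 diabetes cases and
#' controls, for the Caucasian (CAU) and African-American (AFR) cohorts,
#' together with the printed odds ratios.  These frequencies seed
#' [defaultGroupModels()] and the printed odds ratios serve as reference
#' values; cells the source prints as undefined (a zero frequency in one
#' arm) carry `NA`.
#'
#' @return A long-format `data.frame` with columns `marker`, `kind`
#'   (`"diplotype"`, `"haplotype"` or `"snp"`), `race` (`"CAU"`/`"AFR"`),
#'   `freq_t1d`, `freq_control` and `or_printed`.
#' @examples
#' ref <- table2Reference()
#' subset(ref, marker == "rs2476601")
#' @export
table2Reference <- function() {
  dip <- .DIPLOTYPE_LEVELS
  hap <- .HAPLOTYPE_LEVELS
  snp <- .panel_nonhla()$snp_id
  cau <- data.frame(
    marker = c(dip, hap, snp),
    kind = c(rep("diplotype", 6), rep("haplotype", 3), rep("snp", 28)),
    race = "CAU",
    freq_t1d = c(0.2636, 0.0690, 0.0962, 0.2573, 0.1569, 0.1569,
                 0.9822, 0.8800, 0.9927,
                 0.1542, 0.8724, 0.6330, 0.5866, 0.6542, 0.2587, 0.4508,
                 0.5806, 0.4775, 0.9146, 0.8031, 0.8357, 0.3792, 0.7118,
                 0.5254, 0.6697, 0.6392, 0.1395, 0.5071, 0.3686, 0.1955,
                 0.5346, 0.7127, 0.5010, 0.6870, 0.3699, 0.5645, 0.3426),
    freq_control = c(0.0347, 0.0313, 0.0035, 0.1701, 0.1979, 0.5625,
                     0.8802, 0.9100, 0.9790,
                     0.0734, 0.8616, 0.6211, 0.5533, 0.6862, 0.2491, 0.4659,
                     0.5531, 0.4539, 0.8716, 0.6962, 0.6843, 0.3287, 0.6980,
                     0.4608, 0.6695, 0.5773, 0.0942, 0.4846, 0.3564, 0.1598,
                     0.4691, 0.6986, 0.5034, 0.6901, 0.3265, 0.5295, 0.3695),
    or_printed = c(9.95, 2.30, 30.56, 1.69, 0.75, 0.14,
                   7.52, 0.72, 2.91,
                   2.30, 1.10, 1.05, 1.15, 0.86, 1.05, 0.94, 1.12, 1.10,
                   1.58, 1.78, 2.35, 1.25, 1.07, 1.30, 1.00, 1.30, 1.56,
                   1.09, 1.05, 1.28, 1.30, 1.07, 0.99, 0.99, 1.21, 1.15,
                   0.89),
    stringsAsFactors = FALSE)
  afr <- data.frame(
    marker = c(dip, hap, snp),
    kind = cau$kind,
    race = "AFR",
    freq_t1d = c(0.0833, 0.0238, 0.0595, 0.1905, 0.2262, 0.4167,
                 0.9940, 0.9464, 1.0000,
                 0.0179, 0.9458, 0.2143, 0.7927, 0.8095, 0.0783, 0.2262,
                 0.3095, 0.5361, 0.9819, 0.9583, 0.3598, 0.4286, 0.8750,
                 0.1429, 0.1964, 0.7711, 0.1205, 0.4643, 0.1488, 0.1098,
                 0.6905, 0.8855, 0.5714, 0.8012, 0.1627, 0.3512, 0.5882),
    freq_control = c(0.0000, 0.0000, 0.0000, 0.0635, 0.1587, 0.7778,
                     0.9921, 0.9524, 0.9921,
                     0.0154, 0.9385, 0.2109, 0.7000, 0.7846, 0.0769, 0.2000,
                     0.2769, 0.5625, 0.9692, 0.9231, 0.2698, 0.3889, 0.8462,
                     0.0538, 0.2231, 0.7462, 0.2000, 0.5078, 0.1587, 0.1077,
                     0.7540, 0.8516, 0.5000, 0.7538, 0.1385, 0.3385, 0.4393),
    or_printed = c(NA, NA, NA, 3.47, 1.55, 0.20,
                   1.32, 0.88, NA,
                   1.16, 1.14, 1.02, 1.64, 1.17, 1.02, 1.17, 1.17, 0.90,
                   1.72, 1.92, 1.52, 1.18, 1.27, 2.93, 0.85, 1.15, 0.55,
                   0.84, 0.93, 1.02, 0.73, 1.35, 1.33, 1.32, 1.21, 1.06,
                   1.82),
    stringsAsFactors = FALSE)
  rbind(cau, afr)
}

#' Published HLA diplotype by age-at-diagnosis contingency grid
#'
#' Patient counts cross-classifying the six HLA diplotype categories by
#' three age-at-diagnosis bins (under 8, 8 to under 16, 16 and over).
#' Used as the reference input for [buildTable1()] and to parameterise the
#' optional age-by-diplotype mode of the synthetic cohort generator.
#'
#' @return A 3 x 6 integer matrix; rows `lt8`, `8to16`, `ge16`, columns
#'   the six diplotype categories.
#' @examples
#' table1Reference()
#' @export
table1Reference <- function() {
  m <- matrix(c(15, 24, 39, 10,  6, 56,
                30, 33, 62, 29, 15, 60,
                18, 13, 18,  2, 11, 10),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("lt8", "8to16", "ge16"),
                              c("X_X", "DR3_X", "DR4_X", "DR3_DR3",
                                "DR4_DR4", "DR3_DR4")))
  storage.mode(m) <- "integer"
  m
}
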