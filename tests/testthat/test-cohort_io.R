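test_that("wide TSV round-trips dosage matrices, including missing cells", {
  coh <- full_call_cohort(n = 4)
  d <- dosages(coh)
  d["rs689", 2] <- NA
  d["rs2476601", 3] <- 0
  d["rs2664170", 4] <- 2
  coh2 <- GrsCohort(d, snpPanel(coh), sampleData(coh))
  tf <- tempfile(fileext = ".tsv")
  writeGenotypes(coh2, tf)
  back <- readGenotypes(tf, "wide_tsv")
  expect_identical(dim(dosages(back)), dim(d))
  expect_equal(dosages(back)[rownames(d), colnames(d)], d)
})

test_that("wide TSV parsing: NA sentinels, junk cells, duplicate ids", {
  tf <- tempfile(fileext = ".tsv")
  pan <- defaultPanel()[1:6, ]
  writeLines(c(paste(c("sample_id", pan$snp_id), collapse = "\t"),
               paste(c("a", "0", "1", "2", "NA", "x", "1"), collapse = "\t")),
             tf)
  coh <- readGenotypes(tf, "wide_tsv", panel = pan)
  expect_equal(unname(dosages(coh)[, "a"]), c(0, 1, 2, NA, NA, 1))
  writeLines(c(paste(c("sample_id", pan$snp_id[1]), collapse = "\t"),
               "a\t1", "a\t2"), tf)
  expect_error(readGenotypes(tf, "wide_tsv", panel = pan), "duplicate")
  expect_error(readGenotypes(tf, "nonsense"), "unknown")
})

test_that("VCF dosages count risk alleles regardless of REF/ALT orientation", {
  tf <- tempfile(fileext = ".vcf")
  # rs2476601 risk allele A: once as ALT, rs689 risk T as REF;
  # rs1990760 has a half call
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "1\t100\trs2476601\tG\tA\t.\tPASS\t.\tGT\t0/1\t1/1",
    "11\t200\trs689\tT\tA\t.\tPASS\t.\tGT\t0/1\t0/0",
    "2\t300\trs1990760\tC\tT\t.\tPASS\t.\tGT\t./1\t0/1"), tf)
  coh <- readGenotypes(tf, "vcf")
  d <- dosages(coh)
  expect_equal(unname(d["rs2476601", ]), c(1, 2))   # ALT is risk
  expect_equal(unname(d["rs689", ]), c(1, 2))       # REF is risk: flipped
  expect_equal(unname(d["rs1990760", ]), c(NA, 1))  # half call is missing
})

test_that("VCF records that cannot be oriented to the risk allele error", {
  tf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
    "1\t100\trs2476601\tG\tC\t.\tPASS\t.\tGT\t0/1"), tf)
  expect_error(readGenotypes(tf, "vcf"), "rs2476601")
})

test_that("QC excludes missing-HLA and low-call samples with inclusive 90% boundary", {
  coh <- full_call_cohort(n = 4)
  d <- dosages(coh)
  d["rs2187668", 1] <- NA                   # HLA rule
  nonhla <- defaultPanel()$snp_id[!defaultPanel()$is_hla_tag]
  d[nonhla[1:3], 2] <- NA                   # 25/28 = 0.893 < 0.9 -> out
  d[nonhla[1:2], 3] <- NA                   # 26/28 = 0.929 -> retained
  coh <- GrsCohort(d, snpPanel(coh), sampleData(coh))
  qcd <- applyQC(coh)
  rep <- qcReport(qcd)
  expect_equal(colnames(qcd), c("s03", "s04"))
  expect_equal(rep@nExcludedMissingHla, 1L)
  expect_equal(rep@nExcludedLowCall, 1L)
  expect_equal(rep@nInput,
               rep@nRetained + rep@nExcludedMissingHla + rep@nExcludedLowCall)
  # a sample failing both rules is attributed to the HLA rule
  d["rs2187668", 2] <- NA
  rep2 <- qcReport(applyQC(GrsCohort(d, snpPanel(coh), NULL)))
  expect_equal(rep2@nExcludedMissingHla, 2L)
  expect_equal(rep2@nExcludedLowCall, 0L)
})

test_that("QC is idempotent and tolerates an empty cohort", {
  coh <- full_call_cohort(n = 3)
  once <- applyQC(coh)
  twice <- applyQC(once)
  expect_identical(dosages(once), dosages(twice))
  empty <- coh[, FALSE]
  rep <- qcReport(applyQC(empty))
  expect_equal(rep@nInput, 0L)
  expect_equal(rep@nRetained, 0L)
})

test_that("weight configs convert odds ratios to log scale and validate", {
  tf <- tempfile(fileext = ".json")
  write_toy_weight_json(tf, snp_or = list(
    list(snp_id = "snpA", risk_allele = "A", or = 1, chromosome = "1"),
    list(snp_id = "snpB", risk_allele = "G", or = 2.30, chromosome = "X")))
  w <- readWeights(tf)
  expect_equal(unname(w@snpBeta["snpA"]), 0)
  expect_equal(unname(w@snpBeta["snpB"]), log(2.30), tolerance = 1e-12)
  expect_equal(unname(w@snpBeta["snpB"]), 0.8329, tolerance = 1e-4)
  expect_equal(unname(w@chromosome["snpB"]), "X")
  expect_equal(nPanel(w), 5)  # 2 SNPs + 3 haplotype loci

  write_toy_weight_json(tf, drop_category = "DR3_DR3")
  expect_error(readWeights(tf), "DR3_DR3")
  write_toy_weight_json(tf, snp_or = list(
    list(snp_id = "bad", risk_allele = "A", or = -1, chromosome = "1")))
  expect_error(readWeights(tf), "bad")
})

test_that("the shipped default weights load and cover the default panel", {
  w <- defaultWeights()
  pan <- defaultPanel()
  expect_setequal(names(w@snpBeta), pan$snp_id[!pan$is_hla_tag])
  expect_true(all(w@tagSnps %in% pan$snp_id))
  expect_equal(nPanel(w), 31)
})
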