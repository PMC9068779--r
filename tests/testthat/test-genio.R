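test_that("PLINK .raw files round-trip through the genotype matrix", {
  raw <- c("FID IID PAT MAT SEX PHENOTYPE rsA_G rsB_T",
           "f1 s1 0 0 1 -9 0 2",
           "f2 s2 0 0 2 -9 1 1",
           "f3 s3 0 0 1 -9 2 NA")
  path <- withr::local_tempfile(fileext = ".raw")
  writeLines(raw, path)
  gm <- load_genotypes(path, format = "raw")
  expect_equal(dim(gm), c(3L, 2L))
  expect_identical(rownames(gm$calls), c("s1", "s2", "s3"))
  expect_identical(unname(gm$calls[, 1]), c(0L, 1L, 2L))
  expect_identical(unname(gm$calls[3, 2]), NA_integer_)
  expect_identical(gm$variants$rsid, c("rsA", "rsB"))

  out <- withr::local_tempfile(fileext = ".raw")
  write_genotypes_raw(gm, out)
  gm2 <- load_genotypes(out, format = "raw")
  expect_identical(unname(gm2$calls), unname(gm$calls))
  expect_identical(gm2$variants$rsid, gm$variants$rsid)
})

test_that("malformed .raw lines are rejected with their line number", {
  path <- withr::local_tempfile(fileext = ".raw")
  writeLines(c("FID IID PAT MAT SEX PHENOTYPE rs1_G",
               "f1 s1 0 0 1 -9 0",
               "f2 s2 0 0 1 -9"), path)
  expect_error(load_genotypes(path, "raw"), "line 3")
  writeLines(c("FID IID PAT MAT SEX PHENOTYPE rs1_G",
               "f1 s1 0 0 1 -9 5"), path)
  expect_error(load_genotypes(path, "raw"), "line 2")
})

test_that("VCF hard calls are read with biallelic records only", {
  vcf <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=R2,Number=1,Type=Float,Description=\"r2\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", "s1", "s2", "s3", sep = "\t"),
           paste("1", "100", "rs1", "A", "G", ".", "PASS", "R2=0.95",
                 "GT", "0/0", "0/1", "1/1", sep = "\t"),
           paste("1", "200", "rs2", "C", "A,G", ".", "PASS", ".",
                 "GT", "0/1", "0/0", "0/2", sep = "\t"),
           paste("2", "300", "rs3", "T", "C", ".", "PASS", "R2=0.8",
                 "GT", "1|0", "./.", "0|0", sep = "\t"))
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  expect_warning(gm <- load_genotypes(path, "vcf"), "non-biallelic")
  expect_equal(n_variants(gm), 2L)  # multiallelic rs2 skipped
  expect_identical(unname(gm$calls[, "rs1"]), c(0L, 1L, 2L))
  expect_identical(unname(gm$calls[, "rs3"]), c(1L, NA_integer_, 0L))
  expect_equal(gm$variants$info_r2, c(0.95, 0.8))
})

test_that("derive_bmi applies the inclusive 25 kg/m^2 class boundary", {
  at <- derive_bmi(200, 100)
  expect_equal(at$bmi, 25)
  expect_identical(at$bmi_class, "high")
  low <- derive_bmi(175, 70)
  expect_equal(low$bmi, 70 / 1.75^2, tolerance = 1e-12)
  expect_identical(low$bmi_class, "low")
  expect_error(derive_bmi(175, 0), "positive")
  expect_error(derive_bmi(-1, 70), "positive")
})

test_that("derive_bmi is monotone in weight and height", {
  w <- seq(50, 120, by = 5)
  bmi_w <- derive_bmi(170, w)$bmi
  expect_true(all(diff(bmi_w) > 0))
  h <- seq(150, 200, by = 5)
  bmi_h <- derive_bmi(h, 80)$bmi
  expect_true(all(diff(bmi_h) < 0))
})

test_that("phenotype loading drops incomplete rows and counts them", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\theight_cm\tweight_kg\tage\tsex",
               "s1\t175\t70\t60\t1",
               "s2\t160\tNA\t55\t0",
               "s3\t180\t90\t62\t1"), path)
  ph <- load_phenotypes(path)
  expect_equal(nrow(ph), 2L)
  expect_equal(attr(ph, "n_dropped"), 1L)
  expect_equal(ph$bmi[1], 70 / 1.75^2, tolerance = 1e-12)
  expect_identical(ph$bmi_class, c("low", "high"))

  writeLines("sample_id\theight_cm\tweight_kg\tage\tsex", path)
  expect_error(load_phenotypes(path), "no phenotype rows")
})

test_that("sample alignment requires overlap and preserves pairing", {
  co <- null_cohort(20, 3, seed = 11)
  ph <- co$pheno[rev(seq_len(nrow(co$pheno))), ]
  al <- align_samples(co$gm, ph)
  expect_identical(rownames(al$gm$calls), al$pheno$sample_id)
  ph$sample_id <- paste0("other_", ph$sample_id)
  expect_error(align_samples(co$gm, ph), "no overlap")
})

test_that("pair-result tables round-trip losslessly through TSV", {
  res <- data.frame(snp1 = c("rs1", "rs2"), snp2 = c("rs9", "rs7"),
                    method = "regression",
                    statistic = c(1.23456789012345, -0.3),
                    p_nominal = c(3.141592653589793e-8, 0.5),
                    p_adjusted = c(0.000999000999000999, NA),
                    stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_results(res, path)
  back <- read_results(path)
  expect_identical(back$snp1, res$snp1)
  expect_equal(back$statistic, res$statistic, tolerance = 1e-13)
  expect_equal(back$p_nominal, res$p_nominal, tolerance = 1e-13)
  expect_equal(back$p_adjusted, res$p_adjusted, tolerance = 1e-13)

  write_results(res[0, ], path)
  expect_equal(nrow(read_results(path)), 0L)
})

test_that("genotype matrix construction enforces its invariants", {
  calls <- matrix(c(0L, 3L), nrow = 1)
  vars <- data.frame(rsid = c("a", "b"), chrom = "1", pos = c(1L, 2L),
                     ref = "A", alt = "G")
  expect_error(genotype_matrix(calls, vars), "0, 1, 2")
  vars2 <- data.frame(rsid = c("a", "a"), chrom = "1", pos = c(1L, 2L),
                      ref = "A", alt = "G")
  expect_error(genotype_matrix(matrix(0L, 1, 2), vars2), "duplicate rsid")
  vars3 <- data.frame(rsid = c("a", "b"), chrom = "1", pos = c(1L, 2L),
                      ref = "A", alt = "A")
  expect_error(genotype_matrix(matrix(0L, 1, 2), vars3), "identical")
})
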