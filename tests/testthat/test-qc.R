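test_that("HWE exact test handles boundary and symmetric inputs", {
  expect_equal(hwe_exact_test(100, 0, 0), 1)
  expect_equal(hwe_exact_test(0, 0, 57), 1)
  # allele-label symmetry
  for (tr in list(c(10, 10, 10), c(3, 17, 5), c(0, 5, 30))) {
    expect_equal(hwe_exact_test(tr[1], tr[2], tr[3]),
                 hwe_exact_test(tr[3], tr[2], tr[1]), tolerance = 1e-14)
  }
  expect_error(hwe_exact_test(0, 0, 0), "zero")
  expect_error(hwe_exact_test(-1, 2, 3), "non-negative")
})

test_that("HWE exact test matches the enumeration oracle on spot checks", {
  set.seed(42)
  for (k in 1:50) {
    tr <- as.vector(stats::rmultinom(1, sample(5:60, 1), c(1, 1, 1)))
    expect_equal(hwe_exact_test(tr[1], tr[2], tr[3]),
                 hwe_oracle(tr[1], tr[2], tr[3]), tolerance = 1e-12)
  }
})

test_that("HWE test rejects at the nominal rate for HWE genotypes", {
  # 2000 variants simulated at HWE, MAF 0.3, n = 500: the fraction with
  # p <= 0.05 must sit inside the 99% binomial band around 0.05
  cfg <- simulation_config(n_samples = 500, n_variants = 2000, mafs = 0.3,
                           noise_sd = 1, seed = 77)
  gm <- simulate_genotypes(cfg)
  p <- apply(gm$calls, 2, function(g) {
    hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2))
  })
  rate <- mean(p <= 0.05)
  band <- qbinom(c(0.005, 0.995), 2000, 0.05) / 2000
  expect_gte(rate, band[1])
  expect_lte(rate, band[2])
})

test_that("filter_variants excludes by reason and is idempotent", {
  set.seed(5)
  n <- 400
  calls <- cbind(
    rbinom(n, 2, 0.3),                      # clean
    c(rep(1L, n)),                          # all-het: extreme HWE failure
    replace(rbinom(n, 2, 0.3), 1:12, NA),   # 3% missing
    rbinom(n, 2, 0.4))                      # clean, low info_r2
  gm <- toy_gm(calls)
  gm$variants$info_r2 <- c(NA, NA, NA, 0.5)
  fv <- filter_variants(gm, qc_config())
  expect_identical(fv$report$reason[2], "hwe")
  expect_identical(fv$report$reason[3], "call_rate")
  expect_identical(fv$report$reason[4], "info_r2")
  expect_true(fv$report$pass[1])
  expect_identical(fv$gm$variants$rsid, "rs1")
  counts <- attr(fv$report, "counts")
  expect_true(all(diff(counts) <= 0))  # non-increasing across stages

  again <- filter_variants(fv$gm, qc_config())
  expect_identical(again$gm$calls, fv$gm$calls)
  expect_true(all(again$report$pass))
})

test_that("distance pruning keeps the most significant locus per window", {
  v <- data.frame(rsid = c("a", "b", "c", "d"),
                  chrom = c("1", "1", "1", "2"),
                  pos = c(1000000L, 1400000L, 1600001L, 1000000L),
                  assoc_p = c(1e-8, 1e-5, 1e-5, 1e-6),
                  stringsAsFactors = FALSE)
  kept <- prune_by_distance(v, window_bp = 500000L)
  # b is within 400 kb of the stronger a; c is 600,001 bp from a; d is on
  # another chromosome
  expect_identical(kept$rsid, c("a", "c", "d"))

  # boundary: exactly window_bp apart conflicts (inclusive window)
  v2 <- data.frame(rsid = c("x", "y"), chrom = "3",
                   pos = c(1000000L, 1500000L), assoc_p = c(1e-9, 1e-3))
  expect_identical(prune_by_distance(v2, 500000L)$rsid, "x")
  v2$pos[2] <- 1500001L
  expect_identical(prune_by_distance(v2, 500000L)$rsid, c("x", "y"))

  dup <- rbind(v, data.frame(rsid = "a2", chrom = "1", pos = 1000000L,
                             assoc_p = 1e-4))
  expect_warning(prune_by_distance(dup, 500000L), "duplicate")
})

test_that("pruning invariants hold on randomized variant lists", {
  set.seed(99)
  for (rep in 1:30) {
    m <- sample(10:60, 1)
    v <- data.frame(rsid = paste0("v", seq_len(m)),
                    chrom = as.character(sample(1:3, m, replace = TRUE)),
                    pos = sample.int(5000000L, m),
                    assoc_p = runif(m, 1e-10, 1),
                    stringsAsFactors = FALSE)
    v <- v[!duplicated(paste(v$chrom, v$pos)), ]
    kept <- prune_by_distance(v, 500000L)
    for (ch in unique(kept$chrom)) {
      pos <- sort(kept$pos[kept$chrom == ch])
      if (length(pos) > 1) expect_true(all(diff(pos) > 500000L))
    }
    expect_true(v$rsid[which.min(v$assoc_p)] %in% kept$rsid)
  }
})

test_that("stratum allele-frequency bias flags only the skewed variant", {
  set.seed(21)
  n_per <- 20
  strata <- rep(c("CN", "MCI", "Dem"), each = n_per)
  calls <- matrix(rbinom(10 * 3 * n_per, 2, 0.4), ncol = 10)
  # variant 11: all alt alleles in one stratum, none elsewhere
  skew <- c(rep(2L, n_per), rep(0L, 2 * n_per))
  gm <- toy_gm(cbind(calls, skew))
  res <- stratum_af_bias_test(gm, strata, alpha = 0.01)
  expect_true(res$flagged[11])
  expect_false(any(res$flagged[1:10]))
  expect_identical(attr(res, "excluded"), "rs11")
  expect_error(stratum_af_bias_test(gm, rep("CN", 60)), ">=2 strata")
})

test_that("identical strata allele counts give p = 1", {
  calls <- matrix(rep(c(0L, 1L, 2L, 1L), 2), ncol = 1)
  gm <- toy_gm(calls)
  res <- stratum_af_bias_test(gm, rep(c("a", "b"), each = 4))
  expect_equal(res$p_min, 1)
  expect_false(res$flagged)
})
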