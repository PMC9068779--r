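test_that("regression recovers an exact interaction model", {
  set.seed(1)
  n <- 200
  gA <- rbinom(n, 2, 0.5); gB <- rbinom(n, 2, 0.5)
  y <- 1 + gA + gB + 2 * gA * gB
  fit <- regression_epistasis(gA, gB, y)
  expect_equal(fit$beta3, 2, tolerance = 1e-10)
  expect_equal(fit$beta0, 1, tolerance = 1e-10)
  expect_lt(fit$p3, 1e-12)
  expect_equal(fit$r2_full, 1, tolerance = 1e-10)
})

test_that("regression matches the normal-equations oracle with covariates", {
  set.seed(2)
  n <- 300
  for (rep in 1:20) {
    gA <- rbinom(n, 2, 0.4); gB <- rbinom(n, 2, 0.25)
    cv <- cbind(age = runif(n, 40, 70), sex = rbinom(n, 1, 0.5))
    y <- 25 + 0.02 * cv[, 1] + 0.3 * gA + 0.2 * gA * gB + rnorm(n)
    fit <- regression_epistasis(gA, gB, y, cv)
    orc <- regression_oracle(gA, gB, y, cv)
    expect_equal(fit$beta3, orc$beta[length(orc$beta)], tolerance = 1e-9)
    expect_equal(fit$se3, orc$se3, tolerance = 1e-9)
    expect_equal(fit$p3, orc$p3, tolerance = 1e-9)
  }
})

test_that("degenerate designs are rejected", {
  n <- 50
  gB <- rbinom(n, 2, 0.5)
  y <- rnorm(n)
  expect_error(regression_epistasis(rep(0L, n), gB, y), "degenerate")
  expect_error(regression_epistasis(rep(2L, n), rep(1L, n), y),
               "degenerate")
})

test_that("missing calls follow the pairwise-complete policy", {
  set.seed(3)
  n <- 120
  gA <- rbinom(n, 2, 0.5); gB <- rbinom(n, 2, 0.5)
  y <- rnorm(n)
  gA[1:10] <- NA
  fit <- regression_epistasis(gA, gB, y)
  expect_equal(fit$n_used, 110)
  ref <- regression_epistasis(gA[11:n], gB[11:n], y[11:n])
  expect_equal(fit$beta3, ref$beta3, tolerance = 1e-12)
})

test_that("fast-epistasis Z matches the Woolf formula oracle", {
  # construct genotype data whose per-class pseudo-allele tables are known:
  # single-locus carriers laid out cell by cell
  woolf_z <- function(tc, tn) {
    lo <- function(t) log(t[1] * t[4] / (t[2] * t[3]))
    v <- function(t) sum(1 / t)
    (lo(tc) - lo(tn)) / sqrt(v(tc) + v(tn))
  }
  # cases: table (30,10,10,30); controls: (20,20,20,20), built from
  # samples with genotype pairs contributing single units
  build <- function(a, b, cc, d) {
    # each (gA,gB) = (1,1) sample adds 1 to every cell; instead use
    # homozygous carriers adding 2x2 blocks: (2,2) adds 4 to a; (2,0)
    # adds 4 to b; (0,2) adds 4 to cc; (0,0) adds 4 to d
    gA <- c(rep(2L, a), rep(2L, b), rep(0L, cc), rep(0L, d))
    gB <- c(rep(2L, a), rep(0L, b), rep(2L, cc), rep(0L, d))
    list(gA = gA, gB = gB)
  }
  cs <- build(30, 10, 10, 30)
  ct <- build(20, 20, 20, 20)
  gA <- c(cs$gA, ct$gA); gB <- c(cs$gB, ct$gB)
  cls <- c(rep("high", length(cs$gA)), rep("low", length(ct$gA)))
  res <- fast_epistasis(gA, gB, cls)
  expect_equal(res$z,
               woolf_z(4 * c(30, 10, 10, 30), 4 * c(20, 20, 20, 20)),
               tolerance = 1e-12)
})

test_that("fast-epistasis is exactly antisymmetric under class swap", {
  set.seed(4)
  n <- 300
  gA <- rbinom(n, 2, 0.3); gB <- rbinom(n, 2, 0.4)
  cls <- sample(c("high", "low"), n, replace = TRUE)
  a <- fast_epistasis(gA, gB, cls)
  b <- fast_epistasis(gA, gB, ifelse(cls == "high", "low", "high"))
  expect_identical(a$z, -b$z)
  expect_identical(a$p, b$p)

  # identical class tables: duplicate every sample into both classes
  cls2 <- rep(c("high", "low"), each = n)
  same <- fast_epistasis(rep(gA, 2), rep(gB, 2), cls2)
  expect_identical(same$z, 0)
  expect_identical(same$p, 1)

  expect_error(fast_epistasis(gA, gB, rep("high", n)), "empty class")
})

test_that("two-locus ANOVA agrees with a group-sums oracle", {
  set.seed(5)
  n <- 500
  gA <- rbinom(n, 2, 0.4); gB <- rbinom(n, 2, 0.3)
  y <- rnorm(n)
  res <- two_locus_anova(gA, gB, y)
  cell <- interaction(gA, gB, drop = TRUE)
  k <- nlevels(cell)
  grand <- mean(y)
  ssb <- sum(tapply(y, cell, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(tapply(y, cell, function(v) sum((v - mean(v))^2)))
  f_orc <- (ssb / (k - 1)) / (ssw / (n - k))
  expect_equal(res$f, f_orc, tolerance = 1e-10)
  expect_equal(res$p, pf(f_orc, k - 1, n - k, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(res$df_between, res$k_cells - 1L)
  expect_equal(res$df_within, n - res$k_cells)
})

test_that("two-locus ANOVA handles constant and separable phenotypes", {
  set.seed(6)
  gA <- rbinom(200, 2, 0.5); gB <- rbinom(200, 2, 0.5)
  const <- two_locus_anova(gA, gB, rep(3.7, 200))
  expect_equal(const$f, 0)
  expect_equal(const$p, 1)
  # zero noise, one shifted cell: perfect separation
  y <- ifelse(gA == 1 & gB == 1, 5, 0)
  sep <- two_locus_anova(gA, gB, y)
  expect_lt(sep$p, 1e-12)
  expect_error(two_locus_anova(rep(0L, 10), rep(0L, 10), rnorm(10)),
               "single group")
})

test_that("variance partition isolates the interaction share", {
  set.seed(7)
  n <- 2000
  gA <- rbinom(n, 2, 0.5); gB <- rbinom(n, 2, 0.5)
  y <- 2 + 0.5 * gA + rnorm(n)
  vp <- variance_partition(gA, gB, y)
  expect_equal(vp$delta_r2, vp$r2_full - vp$r2_main, tolerance = 1e-15)
  expect_gte(vp$delta_r2, 0)
  y2 <- 2 + 0.5 * gA  # exactly linear in gA alone
  vp2 <- variance_partition(gA, gB, y2)
  expect_equal(vp2$delta_r2, 0, tolerance = 1e-12)
})

test_that("planted interaction variance share matches the analytic value", {
  # product term gA*gB at MAF 0.5 under HWE: main effects absorb the
  # regression of gA*gB on gA and gB; the residual interaction variance
  # share is beta3^2 * var_resid(gA*gB) / var(y)
  set.seed(8)
  n <- 100000
  maf <- 0.5; beta3 <- 0.2
  gA <- rbinom(n, 2, maf); gB <- rbinom(n, 2, maf)
  y <- beta3 * gA * gB + rnorm(n)
  vp <- variance_partition(gA, gB, y)
  # analytic: resid variance of gA*gB on [1,gA,gB] at maf .5 is
  # var(gA*gB) - b_A^2 var(gA) - b_B^2 var(gB) with b_A = cov/var = E[gB]
  vg <- 2 * maf * (1 - maf)
  mu <- 2 * maf
  var_prod <- (vg + mu^2)^2 - (mu^2)^2
  resid_var <- var_prod - 2 * mu^2 * vg
  share <- beta3^2 * resid_var /
    (beta3^2 * var_prod + 1)
  # delta_r2 ~ t^2/n with t^2 noncentral chi-square, ncp ~ n*share:
  # sd(delta_r2) ~ 2*sqrt(n*share)/n
  se_delta <- 2 * sqrt(n * share) / n
  expect_lt(abs(vp$delta_r2 - share), 3 * se_delta)
})

test_that("pairwise scan enumerates, orders and adjusts pairs", {
  co <- null_cohort(300, 3, seed = 12)
  res <- pairwise_scan(co$gm, co$pheno, method = "regression")
  expect_equal(nrow(res), 3L)
  expect_true(all(diff(res$p_nominal) >= 0))
  expect_equal(res$p_adjusted, pmin(1, res$p_nominal * 3),
               tolerance = 1e-15)
  # canonical within-pair order: snp1 precedes snp2 by position
  pos <- setNames(co$gm$variants$pos, co$gm$variants$rsid)
  expect_true(all(pos[res$snp1] < pos[res$snp2]))
})

test_that("scan results are invariant to variant input order", {
  co <- null_cohort(200, 5, seed = 13)
  res1 <- pairwise_scan(co$gm, co$pheno, method = "anova2")
  shuffled <- co$gm[, c(4, 1, 5, 3, 2)]
  res2 <- pairwise_scan(shuffled, co$pheno, method = "anova2")
  expect_equal(res1, res2)
})

test_that("scan validates its inputs", {
  co <- null_cohort(100, 2, seed = 14)
  expect_error(pairwise_scan(co$gm[, 1], co$pheno), "at least 2")
  ph <- co$pheno
  ph$bmi_class <- "high"
  expect_error(pairwise_scan(co$gm, ph, method = "fastepi"),
               "binary class required")
})
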