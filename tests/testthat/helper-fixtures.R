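# Shared helpers: small in-code fixtures for the unit tests.

# Minimal genotype matrix from a calls matrix, metadata autogenerated.
toy_gm <- function(calls, chrom = "1", spacing = 1000000L) {
  m <- ncol(calls)
  genotype_matrix(calls, data.frame(
    rsid = paste0("rs", seq_len(m)),
    chrom = rep_len(chrom, m),
    pos = spacing * seq_len(m),
    ref = "A", alt = "G", stringsAsFactors = FALSE))
}

# Null cohort: independent HWE genotypes, phenotype independent of them.
null_cohort <- function(n, m, maf = 0.3, seed = 1) {
  cfg <- simulation_config(n_samples = n, n_variants = m, mafs = maf,
                           beta0 = 22.3, beta_age = 0.04, beta_sex = 1,
                           noise_sd = 1, seed = seed)
  gm <- simulate_genotypes(cfg)
  list(gm = gm, pheno = simulate_phenotype(gm, cfg), cfg = cfg)
}

# Direct normal-equations OLS oracle for the interaction model.
regression_oracle <- function(gA, gB, y, covariates = NULL) {
  X <- cbind(1, covariates, gA, gB, gA * gB)
  xtx <- crossprod(X)
  beta <- solve(xtx, crossprod(X, y))
  resid <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(resid^2) / df
  covb <- solve(xtx) * sigma2
  j <- ncol(X)
  se3 <- sqrt(covb[j, j])
  t3 <- beta[j] / se3
  list(beta = as.vector(beta), se3 = se3, t3 = t3,
       p3 = 2 * stats::pt(abs(t3), df, lower.tail = FALSE))
}

# Full-enumeration oracle for the HWE exact test: direct log-factorial
# probabilities of every heterozygote count compatible with the allele
# counts, two-sided sum of probabilities <= observed.
hwe_oracle <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  na_ <- 2 * n_hom_ref + n_het  # count of the first allele
  if (na_ == 0 || na_ == 2 * n) return(1)
  hs <- seq(na_ %% 2, min(na_, 2 * n - na_), by = 2)
  logp <- lfactorial(n) - lfactorial((na_ - hs) / 2) - lfactorial(hs) -
    lfactorial(n - hs - (na_ - hs) / 2) + hs * log(2) -
    lchoose(2 * n, na_)
  probs <- exp(logp)
  p_obs <- probs[match(n_het, hs)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-9)]))
}
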