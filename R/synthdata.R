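#' Configuration for the genotype-phenotype simulator
#'
#' Describes a cohort of unrelated samples with independent biallelic
#' variants in Hardy-Weinberg proportions and a BMI-like quantitative
#' phenotype built from an intercept, age and sex covariate effects,
#' sparse additive single-locus effects, an optional planted two-locus
#' interaction, and Gaussian noise. Defaults describe a European-ancestry
#' adult cohort: baseline BMI near 25 kg/m^2, BMI rising ~0.04 kg/m^2 per
#' year of age, ~1 kg/m^2 higher in males, residual SD 4 kg/m^2.
#'
#' @param n_samples Number of samples.
#' @param n_variants Number of variants.
#' @param mafs Minor-allele frequencies in `(0, 0.5]`, recycled across
#'   variants.
#' @param beta0 Phenotype intercept (kg/m^2).
#' @param beta_age,beta_sex Covariate effects (per year; male vs female).
#' @param main_effects Named or indexed numeric vector of per-variant
#'   additive effects (names are variant indices or rsids).
#' @param interaction `NULL`, or a list with `pair` (two variant indices),
#'   `beta3` and `model` (`"product"`: `beta3*gA*gB`; `"xor"`:
#'   `beta3*1[gA+gB odd]`; `"threshold"`: `beta3*1[gA==2 & gB==2]`).
#' @param noise_sd Residual standard deviation, positive.
#' @param age_range Uniform age interval in years.
#' @param bmi_threshold High/low class boundary (kg/m^2).
#' @param seed Integer seed; genotype and phenotype draws are fully
#'   reproducible from it.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_samples, n_variants, mafs = 0.3,
                              beta0 = 25, beta_age = 0.04, beta_sex = 1,
                              main_effects = NULL, interaction = NULL,
                              noise_sd = 4, age_range = c(40, 70),
                              bmi_threshold = 25, seed = 1) {
  stopifnot(n_samples >= 1, n_variants >= 1, noise_sd > 0,
            length(age_range) == 2, age_range[1] <= age_range[2])
  if (any(mafs <= 0 | mafs > 0.5)) {
    stop("minor-allele frequencies must lie in (0, 0.5]")
  }
  if (!is.null(interaction)) {
    stopifnot(is.list(interaction),
              length(interaction$pair) == 2,
              all(interaction$pair >= 1),
              all(interaction$pair <= n_variants),
              interaction$pair[1] != interaction$pair[2])
    interaction$model <- match.arg(interaction$model,
                                   c("product", "xor", "threshold"))
    if (is.null(interaction$beta3)) stop("interaction needs beta3")
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_variants = as.integer(n_variants),
                 mafs = rep_len(mafs, n_variants),
                 beta0 = beta0, beta_age = beta_age, beta_sex = beta_sex,
                 main_effects = main_effects, interaction = interaction,
                 noise_sd = noise_sd, age_range = age_range,
                 bmi_threshold = bmi_threshold, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a genotype matrix under Hardy-Weinberg proportions
#'
#' Each call is the sum of two independent Bernoulli(maf) alleles, drawn
#' independently across variants (no linkage disequilibrium, mirroring a
#' panel pruned to well-separated loci). Variants are placed 1 Mb apart so
#' that distance-based pruning keeps them all.
#'
#' @param cfg A [simulation_config()].
#' @return A [genotype_matrix()], deterministic given `cfg$seed`.
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  n <- cfg$n_samples; m <- cfg$n_variants
  calls <- with_seed(cfg$seed, {
    matrix(stats::rbinom(n * m, size = 2,
                         prob = rep(cfg$mafs, each = n)),
           nrow = n, ncol = m)
  })
  rownames(calls) <- sprintf("S%04d", seq_len(n))
  # 1 Mb spacing, 250 variants per synthetic chromosome so positions stay
  # within integer range for arbitrarily large panels
  idx <- seq_len(m)
  variants <- data.frame(rsid = paste0("rs", idx),
                         chrom = as.character(1L + (idx - 1L) %/% 250L),
                         pos = 1000000L * (1L + (idx - 1L) %% 250L),
                         ref = "A", alt = "G", info_r2 = NA_real_,
                         stringsAsFactors = FALSE)
  genotype_matrix(calls, variants)
}

#' Simulate a BMI-like phenotype over a genotype matrix
#'
#' Builds `bmi = beta0 + beta_age*age + beta_sex*sex + sum(main effects)
#' + interaction + N(0, noise_sd^2)` with age uniform over `age_range` and
#' sex Bernoulli(1/2), then derives the high/low class at
#' `cfg$bmi_threshold`. The interaction term follows `cfg$interaction`
#' (product, xor or threshold form).
#'
#' @param gm A [genotype_matrix()] (typically from [simulate_genotypes()]).
#' @param cfg The same [simulation_config()].
#' @return A `phenotype_table` with `sample_id`, `age`, `sex`, `bmi`,
#'   `bmi_class`.
#' @export
simulate_phenotype <- function(gm, cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  n <- n_samples(gm)
  if (n != cfg$n_samples || n_variants(gm) != cfg$n_variants) {
    stop("genotype matrix dimensions do not match the configuration")
  }
  draws <- with_seed(cfg$seed + 1L, {
    list(age = stats::runif(n, cfg$age_range[1], cfg$age_range[2]),
         sex = stats::rbinom(n, 1, 0.5),
         eps = stats::rnorm(n, 0, cfg$noise_sd))
  })
  bmi <- cfg$beta0 + cfg$beta_age * draws$age + cfg$beta_sex * draws$sex +
    draws$eps
  if (!is.null(cfg$main_effects) && length(cfg$main_effects)) {
    eff <- cfg$main_effects
    idx <- if (is.null(names(eff))) seq_along(eff)
           else match(names(eff), gm$variants$rsid)
    if (anyNA(idx)) {
      idx2 <- suppressWarnings(as.integer(names(eff)))
      idx[is.na(idx)] <- idx2[is.na(idx)]
    }
    if (anyNA(idx)) stop("main_effects name not found among variants")
    for (k in seq_along(eff)) {
      bmi <- bmi + eff[k] * gm$calls[, idx[k]]
    }
  }
  if (!is.null(cfg$interaction)) {
    gA <- gm$calls[, cfg$interaction$pair[1]]
    gB <- gm$calls[, cfg$interaction$pair[2]]
    term <- switch(cfg$interaction$model,
                   product = gA * gB,
                   xor = as.numeric((gA + gB) %% 2 == 1),
                   threshold = as.numeric(gA == 2 & gB == 2))
    bmi <- bmi + cfg$interaction$beta3 * term
  }
  out <- data.frame(sample_id = rownames(gm$calls),
                    age = draws$age, sex = as.integer(draws$sex),
                    bmi = bmi,
                    bmi_class = ifelse(bmi >= cfg$bmi_threshold,
                                       "high", "low"),
                    stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- 0L
  class(out) <- c("phenotype_table", "data.frame")
  out
}

#' Canonical simulation configurations
#'
#' Returns the [simulation_config()] behind each named fixture of
#' [make_fixture()]. Sizes and effect scales are fixed here once and used
#' unchanged throughout the package's validation suite.
#'
#' @param name One of `"null"`, `"planted_product"`, `"planted_xor"`.
#' @param seed Integer seed.
#' @return A [simulation_config()].
#' @export
fixture_config <- function(name, seed = 1) {
  switch(name,
    # beta0 centres mean BMI on the 25 kg/m^2 class boundary after the
    # expected covariate contribution (0.04*55 + 1*0.5), so both classes
    # are well populated
    null = simulation_config(
      n_samples = 1000, n_variants = 10, mafs = 0.3,
      beta0 = 22.3, beta_age = 0.04, beta_sex = 1, noise_sd = 1,
      seed = seed),
    planted_product = simulation_config(
      n_samples = 2000, n_variants = 20, mafs = 0.3,
      beta0 = 22.3, beta_age = 0.04, beta_sex = 1, noise_sd = 1,
      interaction = list(pair = c(5, 12), beta3 = 0.5,
                         model = "product"),
      seed = seed),
    planted_xor = simulation_config(
      n_samples = 900, n_variants = 10, mafs = c(rep(0.3, 2), 0.5, 0.5,
                                                 rep(0.3, 6)),
      beta0 = 20, beta_age = 0, beta_sex = 0, noise_sd = 0.5,
      interaction = list(pair = c(3, 4), beta3 = 10, model = "xor"),
      seed = seed),
    stop("unknown fixture: ", name))
}

#' Write a named simulation fixture to disk
#'
#' Generates one of the canonical test cohorts and writes it as PLINK .raw
#' genotypes plus a TSV phenotype table:
#' \describe{
#'   \item{`null`}{n = 1000, 10 variants, no genotype effects.}
#'   \item{`planted_product`}{n = 2000, 20 variants, product interaction
#'     `beta3 = 0.5` (= 0.5 residual SD) planted between rs5 and rs12.}
#'   \item{`planted_xor`}{n = 900, 10 variants; rs3 x rs4 xor interaction
#'     of 10 kg/m^2 against residual SD 0.5, i.e. complete penetrance of
#'     the high/low class.}
#'   \item{`two_cohort`}{two independent `planted_product`-style cohorts
#'     (the second cohort's interaction can be switched off with
#'     `second_null = TRUE` to emulate a non-replicating discovery).}
#' }
#'
#' @param name One of `"null"`, `"planted_product"`, `"planted_xor"`,
#'   `"two_cohort"`.
#' @param seed Integer seed.
#' @param dir Output directory (created if needed).
#' @param second_null For `"two_cohort"`: plant the interaction only in
#'   cohort 1.
#' @return Invisibly, a named list of the written file paths.
#' @export
make_fixture <- function(name = c("null", "planted_product",
                                  "planted_xor", "two_cohort"),
                         seed = 1, dir = tempdir(), second_null = FALSE) {
  name <- match.arg(name)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_cohort <- function(cfg, prefix) {
    gm <- simulate_genotypes(cfg)
    ph <- simulate_phenotype(gm, cfg)
    g_path <- file.path(dir, paste0(prefix, ".raw"))
    p_path <- file.path(dir, paste0(prefix, "_pheno.tsv"))
    write_genotypes_raw(gm, g_path)
    write_phenotypes(ph, p_path)
    c(genotypes = g_path, phenotypes = p_path)
  }
  if (name == "two_cohort") {
    cfg1 <- fixture_config("planted_product", seed = seed)
    cfg2 <- fixture_config("planted_product", seed = seed + 1000L)
    if (second_null) cfg2$interaction <- NULL
    paths <- c(write_cohort(cfg1, "cohort1"),
               write_cohort(cfg2, "cohort2"))
    names(paths) <- c("genotypes", "phenotypes",
                      "genotypes2", "phenotypes2")
  } else {
    paths <- write_cohort(fixture_config(name, seed = seed), name)
  }
  invisible(as.list(paths))
}
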