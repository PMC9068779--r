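# Internal: run `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Internal: OLS via QR with coefficient covariance; errors on rank
# deficiency (monomorphic genotype, collinear covariates, ...).
ols_fit <- function(X, y) {
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p) stop("degenerate design: n <= number of parameters")
  dec <- qr(X)
  if (dec$rank < p) stop("degenerate design: rank-deficient model matrix")
  coef <- qr.coef(dec, y)
  fitted <- as.vector(X %*% coef)
  resid <- y - fitted
  rss <- sum(resid^2)
  df <- n - p
  sigma2 <- rss / df
  R <- qr.R(dec)
  xtx_inv <- chol2inv(R)
  se <- sqrt(pmax(diag(xtx_inv) * sigma2, 0))
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 0
  list(coef = coef, se = se, rss = rss, df = df, r2 = r2,
       n = n, p = p, fitted = fitted)
}

adj_r2 <- function(r2, n, p_predictors) {
  1 - (1 - r2) * (n - 1) / (n - p_predictors - 1)
}

#' Linear-regression test of pairwise epistasis
#'
#' Fits, by ordinary least squares, the two-locus interaction model
#' \deqn{Y = \beta_0 + \beta_1 g_A + \beta_2 g_B + \beta_3 g_A g_B}
#' (optionally with covariate columns between the intercept and the
#' genotype terms), where \eqn{g_A} and \eqn{g_B} are ALT-allele counts.
#' The interaction coefficient \eqn{\beta_3} is tested with a two-sided t
#' test. Rows with a missing value in any used variable are dropped
#' (pairwise-complete policy).
#'
#' @param gA,gB Integer genotype vectors in `{0, 1, 2, NA}`.
#' @param y Quantitative phenotype vector.
#' @param covariates Optional numeric matrix/data frame of covariates.
#' @return An object of class `regression_fit`: coefficients `beta0`..
#'   `beta3`, `se3`, `t3`, `p3`, raw and adjusted R-squared for the
#'   main-effects and full models, and `n_used`.
#' @export
regression_epistasis <- function(gA, gB, y, covariates = NULL) {
  n <- length(y)
  stopifnot(length(gA) == n, length(gB) == n)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == n)
  }
  keep <- !is.na(gA) & !is.na(gB) & !is.na(y)
  if (!is.null(covariates)) keep <- keep & stats::complete.cases(covariates)
  gA <- as.numeric(gA[keep]); gB <- as.numeric(gB[keep]); y <- y[keep]
  cv <- if (is.null(covariates)) NULL else covariates[keep, , drop = FALSE]
  n_used <- length(y)
  X_main <- cbind(`(Intercept)` = 1, cv, gA = gA, gB = gB)
  X_full <- cbind(X_main, `gA:gB` = gA * gB)
  fit_full <- ols_fit(X_full, y)
  fit_main <- ols_fit(X_main, y)
  p_full <- ncol(X_full)
  j3 <- p_full  # interaction is the last column
  beta3 <- unname(fit_full$coef[j3])
  se3 <- fit_full$se[j3]
  t3 <- beta3 / se3
  p3 <- 2 * stats::pt(abs(t3), df = fit_full$df, lower.tail = FALSE)
  p3 <- max(p3, .Machine$double.xmin)
  structure(list(
    beta0 = unname(fit_full$coef[1]),
    beta1 = unname(fit_full$coef[j3 - 2]),
    beta2 = unname(fit_full$coef[j3 - 1]),
    beta3 = beta3, se3 = se3, t3 = t3, p3 = p3,
    coef = fit_full$coef,
    r2_main = fit_main$r2, r2_full = fit_full$r2,
    r2_adj_main = adj_r2(fit_main$r2, n_used, ncol(X_main) - 1),
    r2_adj_full = adj_r2(fit_full$r2, n_used, p_full - 1),
    n_used = n_used), class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat("two-locus regression interaction fit\n")
  cat(sprintf("  beta3 = %.4g (se %.3g), t = %.3f, p = %.3g, n = %d\n",
              x$beta3, x$se3, x$t3, x$p3, x$n_used))
  cat(sprintf("  R2 main %.5f -> full %.5f (delta %.3g)\n",
              x$r2_main, x$r2_full, x$r2_full - x$r2_main))
  invisible(x)
}

#' Case/control allele-count odds-ratio Z test ("fast epistasis")
#'
#' Within each phenotype class, the two loci's ALT-allele counts are
#' cross-tabulated into a 2x2 pseudo-allele table (each sample contributes
#' the outer product of `(gA, 2-gA)` and `(gB, 2-gB)`), giving an
#' inter-locus odds ratio R in the high-BMI class and S in the low class.
#' The test statistic is
#' \deqn{Z = (\log R - \log S) / \sqrt{V_R + V_S}}
#' with Woolf variances (sum of reciprocal cell counts). If any cell of a
#' table is zero, 0.5 is added to all four cells of that table
#' (Haldane-Anscombe).
#'
#' @param gA,gB Integer genotype vectors in `{0, 1, 2}` (no missing).
#' @param bmi_class Character vector of `"high"`/`"low"` labels (or a
#'   logical vector, `TRUE` = case).
#' @return An object of class `fastepi_result` with the per-class log odds
#'   ratios and variances, `z` and the two-sided normal `p`.
#' @export
fast_epistasis <- function(gA, gB, bmi_class) {
  if (is.logical(bmi_class)) {
    bmi_class <- ifelse(bmi_class, "high", "low")
  }
  keep <- !is.na(gA) & !is.na(gB) & !is.na(bmi_class)
  gA <- gA[keep]; gB <- gB[keep]; bmi_class <- bmi_class[keep]
  if (!any(bmi_class == "high") || !any(bmi_class == "low")) {
    stop("empty class: need both high and low samples")
  }
  table4 <- function(idx) {
    a <- sum(gA[idx] * gB[idx])              # alt-alt
    b <- sum(gA[idx] * (2 - gB[idx]))        # alt-ref
    cc <- sum((2 - gA[idx]) * gB[idx])       # ref-alt
    d <- sum((2 - gA[idx]) * (2 - gB[idx]))  # ref-ref
    cells <- c(a, b, cc, d)
    if (any(cells == 0)) cells <- cells + 0.5
    cells
  }
  tc <- table4(bmi_class == "high")
  tn <- table4(bmi_class == "low")
  log_or <- function(t) log(t[1]) + log(t[4]) - log(t[2]) - log(t[3])
  var_lo <- function(t) sum(1 / t)
  lr <- log_or(tc); ls <- log_or(tn)
  vr <- var_lo(tc); vs <- var_lo(tn)
  z <- (lr - ls) / sqrt(vr + vs)
  p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  p <- max(p, .Machine$double.xmin)
  structure(list(log_or_cases = lr, log_or_controls = ls,
                 var_log_or_cases = vr, var_log_or_controls = vs,
                 z = z, p = p), class = "fastepi_result")
}

#' @export
print.fastepi_result <- function(x, ...) {
  cat(sprintf("fast-epistasis: log OR high %.4f, low %.4f, Z = %.3f, p = %.3g\n",
              x$log_or_cases, x$log_or_controls, x$z, x$p))
  invisible(x)
}

#' Two-locus ANOVA across joint-genotype cells
#'
#' One-way ANOVA of the quantitative phenotype across the occupied cells of
#' the 3x3 joint-genotype grid of the two loci (the association statistic
#' that exhaustive two-locus ANOVA scanners permute).
#'
#' @param gA,gB Integer genotype vectors in `{0, 1, 2, NA}`.
#' @param y Quantitative phenotype.
#' @return An object of class `anova2_result` with `f`, `df_between`,
#'   `df_within`, `p` and `k_cells` (number of occupied cells).
#' @export
two_locus_anova <- function(gA, gB, y) {
  keep <- !is.na(gA) & !is.na(gB) & !is.na(y)
  gA <- gA[keep]; gB <- gB[keep]; y <- y[keep]
  cell <- factor(3L * gA + gB)
  k <- nlevels(cell)
  n <- length(y)
  if (k < 2) stop("single group: all samples share one genotype cell")
  if (n <= k) stop("fewer samples than occupied cells")
  grand <- mean(y)
  tss <- sum((y - grand)^2)
  if (tss == 0) {  # constant phenotype: no variance to partition
    return(structure(list(f = 0, df_between = k - 1L, df_within = n - k,
                          p = 1, k_cells = k), class = "anova2_result"))
  }
  fit <- stats::lm(y ~ cell)
  # anova() warns on an essentially perfect fit; Inf/0 handled below
  an <- suppressWarnings(stats::anova(fit))
  f <- an$`F value`[1]
  p <- an$`Pr(>F)`[1]
  if (!is.finite(f)) {  # zero within-cell variance, perfect separation
    f <- Inf
    p <- 0
  }
  p <- max(p, .Machine$double.xmin)
  structure(list(f = f, df_between = k - 1L, df_within = n - k,
                 p = p, k_cells = k), class = "anova2_result")
}

#' @export
print.anova2_result <- function(x, ...) {
  cat(sprintf("two-locus ANOVA: F(%d, %d) = %.3f over %d cells, p = %.3g\n",
              x$df_between, x$df_within, x$f, x$k_cells, x$p))
  invisible(x)
}

#' Main-effects versus interaction variance partition
#'
#' Compares the phenotypic variance explained by the covariates-plus-main-
#' effects model with the model that adds the interaction term, reporting
#' raw and adjusted R-squared for both and the interaction's incremental
#' share `delta_r2 = r2_full - r2_main` (non-negative for raw R-squared of
#' nested models; the adjusted delta may be negative when the interaction
#' adds nothing).
#'
#' @inheritParams regression_epistasis
#' @return A list with `r2_main`, `r2_full`, `delta_r2`, `r2_adj_main`,
#'   `r2_adj_full`, `delta_r2_adj` and `n_used`.
#' @export
variance_partition <- function(gA, gB, y, covariates = NULL) {
  fit <- regression_epistasis(gA, gB, y, covariates)
  list(r2_main = fit$r2_main, r2_full = fit$r2_full,
       delta_r2 = fit$r2_full - fit$r2_main,
       r2_adj_main = fit$r2_adj_main, r2_adj_full = fit$r2_adj_full,
       delta_r2_adj = fit$r2_adj_full - fit$r2_adj_main,
       n_used = fit$n_used)
}

# Internal: canonical (chrom, pos, rsid) variant order.
canonical_variant_order <- function(variants) {
  suppress <- function(x) suppressWarnings(as.integer(x))
  chrom_num <- suppress(sub("^chr", "", variants$chrom))
  order(is.na(chrom_num), chrom_num, variants$chrom, variants$pos,
        variants$rsid)
}

#' Exhaustive pairwise interaction scan
#'
#' Applies one closed-form interaction statistic to all variant pairs of a
#' QC-passed genotype matrix. Pairs are reported in canonical
#' (chrom, pos) order within each pair, results are sorted by ascending
#' nominal p (ties broken by pair order), and a Bonferroni-adjusted p over
#' the `m(m-1)/2` tests is attached. Pairs whose statistic cannot be
#' computed (for instance a monomorphic locus) are returned with `NA` and
#' sort last.
#'
#' @param gm A [genotype_matrix()].
#' @param pheno A phenotype table aligned or alignable with `gm` (shared
#'   `sample_id`s).
#' @param method One of `"regression"`, `"fastepi"`, `"anova2"`.
#' @param covariates Character vector of phenotype columns to adjust for in
#'   the regression method (default none, matching tools that do not
#'   support covariates in interaction scans).
#' @return A data frame of pair results: `snp1`, `snp2`, `method`,
#'   `statistic`, `p_nominal`, `p_adjusted`.
#' @export
pairwise_scan <- function(gm, pheno,
                          method = c("regression", "fastepi", "anova2"),
                          covariates = NULL) {
  method <- match.arg(method)
  if (n_variants(gm) < 2) stop("need at least 2 variants to scan pairs")
  al <- align_samples(gm, pheno)
  gm <- al$gm; pheno <- al$pheno
  ord <- canonical_variant_order(gm$variants)
  gm <- gm[, ord]
  m <- n_variants(gm)
  if (method == "fastepi") {
    if (!("bmi_class" %in% names(pheno)) ||
        length(unique(pheno$bmi_class)) < 2) {
      stop("binary class required: fastepi needs both bmi_class levels")
    }
  }
  cv <- NULL
  if (!is.null(covariates)) {
    missing_cv <- setdiff(covariates, names(pheno))
    if (length(missing_cv)) stop("unknown covariate: ", missing_cv[1])
    cv <- as.matrix(pheno[, covariates, drop = FALSE])
  }
  y <- pheno$bmi
  cls <- pheno$bmi_class
  n_pairs <- m * (m - 1) / 2
  snp1 <- character(n_pairs); snp2 <- character(n_pairs)
  stat <- numeric(n_pairs); pval <- numeric(n_pairs)
  k <- 0L
  for (i in seq_len(m - 1)) {
    gA <- gm$calls[, i]
    for (j in seq((i + 1), m)) {
      k <- k + 1L
      snp1[k] <- gm$variants$rsid[i]
      snp2[k] <- gm$variants$rsid[j]
      gB <- gm$calls[, j]
      res <- tryCatch(switch(method,
        regression = {
          fit <- regression_epistasis(gA, gB, y, cv)
          c(fit$t3, fit$p3)
        },
        fastepi = {
          fit <- fast_epistasis(gA, gB, cls)
          c(fit$z, fit$p)
        },
        anova2 = {
          fit <- two_locus_anova(gA, gB, y)
          c(fit$f, fit$p)
        }), error = function(e) c(NA_real_, NA_real_))
      stat[k] <- res[1]; pval[k] <- res[2]
    }
  }
  out <- data.frame(snp1 = snp1, snp2 = snp2, method = method,
                    statistic = stat, p_nominal = pval,
                    p_adjusted = pmin(1, pval * n_pairs),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_nominal, seq_len(n_pairs), na.last = TRUE), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
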