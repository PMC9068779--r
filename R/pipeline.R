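#' Run configuration for the discovery/replication workflow
#'
#' Bundles the inputs and knobs of the end-to-end pipeline: QC settings,
#' the interaction methods to run, permutation depth, the consensus and
#' replication gates, and the seed. Genotype/phenotype entries may be file
#' paths (PLINK .raw and TSV) or in-memory objects.
#'
#' @param genotypes,phenotypes Discovery-cohort inputs.
#' @param genotypes2,phenotypes2 Optional replication-cohort inputs.
#' @param qc A [qc_config()].
#' @param methods Methods to run: subset of `"regression"`, `"fastepi"`,
#'   `"anova2"`, `"mdr"`, `"gmdr"`.
#' @param perms Permutations per method (default 1000).
#' @param min_methods Consensus support threshold (default 2).
#' @param alpha Significance level (default 0.05).
#' @param cvc_min Cross-validation consistency gate for MDR/GMDR
#'   (default 7 of `k_folds`).
#' @param k_folds Cross-validation folds (default 10).
#' @param covariates Covariate columns for regression/GMDR (default
#'   `NULL` for the closed-form scans; GMDR always uses age and sex).
#' @param seed Integer seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(genotypes, phenotypes, genotypes2 = NULL,
                       phenotypes2 = NULL, qc = qc_config(),
                       methods = c("regression", "fastepi", "anova2",
                                   "mdr", "gmdr"),
                       perms = 1000, min_methods = 2, alpha = 0.05,
                       cvc_min = 7, k_folds = 10, covariates = NULL,
                       seed = 1) {
  if (!length(methods)) stop("config error: methods must be non-empty")
  methods <- match.arg(methods,
                       c("regression", "fastepi", "anova2", "mdr", "gmdr"),
                       several.ok = TRUE)
  if (perms < 19) stop("config error: perms must be >= 19")
  structure(list(genotypes = genotypes, phenotypes = phenotypes,
                 genotypes2 = genotypes2, phenotypes2 = phenotypes2,
                 qc = qc, methods = methods, perms = perms,
                 min_methods = min_methods, alpha = alpha,
                 cvc_min = cvc_min, k_folds = k_folds,
                 covariates = covariates, seed = as.integer(seed)),
            class = "run_config")
}

as_genotype_matrix <- function(x) {
  if (inherits(x, "genotype_matrix")) return(x)
  if (is.character(x)) {
    fmt <- if (grepl("\\.vcf(\\.gz)?$", x)) "vcf" else "raw"
    return(load_genotypes(x, format = fmt))
  }
  stop("expected a genotype_matrix or a file path")
}

as_phenotype_table <- function(x) {
  if (is.character(x)) return(load_phenotypes(x))
  if (is.data.frame(x)) return(x)
  stop("expected a phenotype table or a file path")
}

#' Discovery stage: QC, multi-method scan, permutation, consensus
#'
#' Runs the discovery arm of the workflow on cohort 1: variant QC, one
#' exhaustive pairwise scan per closed-form method with family-wise
#' permutation adjustment, an MDR and/or GMDR search with its permutation
#' test (gated on cross-validation consistency), and the cross-method
#' consensus. Deterministic given `cfg$seed`.
#'
#' @param cfg A [run_config()].
#' @param quiet Suppress progress messages (default `TRUE`).
#' @return A list of class `discovery_result`: `gm` (QC-passed genotypes),
#'   `pheno`, `qc_report`, `results` (named per-method tables), `models`
#'   (fitted `cdr_model`s), `consensus`, and a structured `log` data frame
#'   of stage/count records.
#' @export
run_discovery <- function(cfg, quiet = TRUE) {
  stopifnot(inherits(cfg, "run_config"))
  log <- list()
  note <- function(stage, detail, count = NA_integer_) {
    log[[length(log) + 1]] <<- data.frame(stage = stage, detail = detail,
                                          count = count,
                                          stringsAsFactors = FALSE)
    if (!quiet) message(sprintf("[%s] %s (%s)", stage, detail, count))
  }
  gm <- as_genotype_matrix(cfg$genotypes)
  pheno <- as_phenotype_table(cfg$phenotypes)
  note("load", "variants loaded", n_variants(gm))
  note("load", "phenotype rows", nrow(pheno))
  al <- align_samples(gm, pheno)
  gm <- al$gm; pheno <- al$pheno
  note("merge", "samples with genotype and phenotype", nrow(pheno))
  fv <- filter_variants(gm, cfg$qc)
  gm <- fv$gm
  note("qc", "variants passing QC", n_variants(gm))
  if (n_variants(gm) == 0) stop("zero variants survive QC")
  results <- list()
  models <- list()
  closed <- intersect(cfg$methods, c("regression", "fastepi", "anova2"))
  for (meth in closed) {
    scan_fn <- local({
      mm <- meth; cv <- cfg$covariates
      function(g, ph) pairwise_scan(g, ph, method = mm, covariates = cv)
    })
    res <- permutation_adjust(scan_fn, gm, pheno, B = cfg$perms,
                              seed = cfg$seed)
    results[[meth]] <- res
    note("scan", paste0(meth, ": pairs with adjusted p < alpha"),
         sum(res$p_adjusted < cfg$alpha, na.rm = TRUE))
  }
  for (mode in intersect(cfg$methods, c("mdr", "gmdr"))) {
    mod <- cdr_permutation(gm, pheno, mode = mode, B = cfg$perms,
                           k_folds = cfg$k_folds, seed = cfg$seed)
    models[[mode]] <- mod
    pass <- mod$cvc >= cfg$cvc_min && mod$perm_p < cfg$alpha
    results[[mode]] <- if (pass) {
      data.frame(snp1 = mod$pair[1], snp2 = mod$pair[2], method = mode,
                 statistic = mod$test_ba, p_nominal = NA_real_,
                 p_adjusted = mod$perm_p, stringsAsFactors = FALSE)
    } else {
      data.frame(snp1 = character(0), snp2 = character(0),
                 method = character(0), statistic = numeric(0),
                 p_nominal = numeric(0), p_adjusted = numeric(0),
                 stringsAsFactors = FALSE)
    }
    note("cdr", sprintf("%s: pair %s x %s, CVC %d, perm p %.4g", mode,
                        mod$pair[1], mod$pair[2], mod$cvc, mod$perm_p),
         as.integer(pass))
  }
  consensus <- consensus_pairs(results, min_methods = cfg$min_methods,
                               alpha = cfg$alpha)
  note("consensus", sprintf("pairs supported by >= %d methods",
                            cfg$min_methods), nrow(consensus))
  structure(list(gm = gm, pheno = pheno, qc_report = fv$report,
                 results = results, models = models,
                 consensus = consensus, log = do.call(rbind, log),
                 cfg = cfg),
            class = "discovery_result")
}

#' Replication stage: re-test consensus pairs in cohort 2
#'
#' Applies the discovery-to-replication gate on the second cohort, then
#' runs the genotype-combination enrichment analysis and the main-versus-
#' interaction variance partition on every replicated pair.
#'
#' @param cfg The [run_config()] (must carry `genotypes2`/`phenotypes2`).
#' @param discovery A `discovery_result` from [run_discovery()].
#' @param quiet Suppress progress messages.
#' @return A list of class `replication_result`: `replication` (per-pair
#'   status table), `combos` and `variance` (named by `snp1|snp2`, for
#'   replicated pairs), `qc_report`, `log`.
#' @export
run_replication <- function(cfg, discovery, quiet = TRUE) {
  stopifnot(inherits(cfg, "run_config"),
            inherits(discovery, "discovery_result"))
  if (is.null(cfg$genotypes2) || is.null(cfg$phenotypes2)) {
    stop("config error: replication requires genotypes2 and phenotypes2")
  }
  gm2 <- as_genotype_matrix(cfg$genotypes2)
  pheno2 <- as_phenotype_table(cfg$phenotypes2)
  al <- align_samples(gm2, pheno2)
  gm2 <- al$gm; pheno2 <- al$pheno
  fv <- filter_variants(gm2, cfg$qc)
  gm2 <- fv$gm
  if (!nrow(discovery$consensus)) {
    empty <- data.frame(snp1 = character(0), snp2 = character(0),
                        status = character(0), best_method = character(0),
                        best_p_adjusted = numeric(0),
                        stringsAsFactors = FALSE)
    return(structure(list(replication = empty, combos = list(),
                          variance = list(), qc_report = fv$report),
                     class = "replication_result"))
  }
  rep_tab <- replication_check(discovery$consensus, gm2, pheno2,
                               methods = cfg$methods, B = cfg$perms,
                               alpha = cfg$alpha, cvc_min = cfg$cvc_min,
                               k_folds = cfg$k_folds,
                               covariates = cfg$covariates,
                               seed = cfg$seed)
  combos <- list()
  variance <- list()
  for (r in which(rep_tab$status == "replicated")) {
    s1 <- rep_tab$snp1[r]; s2 <- rep_tab$snp2[r]
    gA <- gm2$calls[, s1]; gB <- gm2$calls[, s2]
    key <- paste(s1, s2, sep = "|")
    combos[[key]] <- combination_enrichment(
      combination_counts(gA, gB, pheno2$bmi_class), alpha = cfg$alpha)
    cv <- as.matrix(pheno2[, c("age", "sex")])
    variance[[key]] <- variance_partition(gA, gB, pheno2$bmi, cv)
  }
  structure(list(replication = rep_tab, combos = combos,
                 variance = variance, qc_report = fv$report),
            class = "replication_result")
}
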