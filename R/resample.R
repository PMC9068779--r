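#' Family-wise permutation adjustment for a pairwise scan
#'
#' Permutes the phenotype rows (with covariates) against the genotype rows
#' `B` times, recomputes the scan each time, and compares every observed
#' nominal p-value with the null distribution of the per-permutation
#' minimum p (max-statistic / min-p family-wise procedure):
#' `p_adjusted = (1 + #[min-p null <= p_observed]) / (1 + B)`.
#'
#' @param scan_fn Function `(gm, pheno) -> data.frame` returning at least
#'   `snp1`, `snp2`, `p_nominal` (for instance a closure over
#'   [pairwise_scan()]).
#' @param gm A [genotype_matrix()].
#' @param pheno A phenotype table sharing sample ids with `gm`.
#' @param B Number of permutations (`>= 19`, default 1000).
#' @param seed Integer seed.
#' @return The observed scan data frame with `p_adjusted` replaced by the
#'   permutation-adjusted value; the null minima are attached as attribute
#'   `"null_min_p"`.
#' @export
permutation_adjust <- function(scan_fn, gm, pheno, B = 1000, seed = 1) {
  if (B < 19) stop("need B >= 19 permutations")
  obs <- scan_fn(gm, pheno)
  if (!all(c("snp1", "snp2", "p_nominal") %in% names(obs))) {
    stop("scan_fn must return snp1, snp2 and p_nominal")
  }
  n <- nrow(pheno)
  value_cols <- setdiff(names(pheno), "sample_id")
  perms <- with_seed(seed, lapply(seq_len(B), function(b) sample.int(n)))
  null_min <- vapply(seq_len(B), function(b) {
    ph <- pheno
    ph[value_cols] <- pheno[perms[[b]], value_cols]
    min(scan_fn(gm, ph)$p_nominal, na.rm = TRUE)
  }, numeric(1))
  obs$p_adjusted <- vapply(obs$p_nominal, function(p) {
    if (is.na(p)) return(NA_real_)
    (1 + sum(null_min <= p)) / (1 + B)
  }, numeric(1))
  attr(obs, "null_min_p") <- null_min
  obs
}

# Order-free pair key.
pair_key <- function(snp1, snp2) {
  paste(pmin(snp1, snp2), pmax(snp1, snp2), sep = "|")
}

#' Consensus of significant pairs across methods
#'
#' A pair enters the consensus report when at least `min_methods` distinct
#' methods flag it significant (permutation-adjusted p below `alpha`, or
#' any method-specific gate applied upstream by passing pre-filtered
#' tables). Pair identity ignores the within-pair order.
#'
#' @param results Named list of per-method pair-result data frames (each
#'   with `snp1`, `snp2` and, unless pre-filtered, `p_adjusted`).
#' @param min_methods Minimum number of supporting methods (default 2).
#' @param alpha Per-method significance gate on `p_adjusted` (default
#'   0.05); rows with missing `p_adjusted` are treated as pre-filtered,
#'   i.e. already significant.
#' @return A data frame of class `consensus_report`: `snp1`, `snp2`,
#'   `n_methods`, `methods` (comma separated), `min_p_adjusted`.
#' @export
consensus_pairs <- function(results, min_methods = 2, alpha = 0.05) {
  if (!length(results)) {
    return(empty_consensus(min_methods))
  }
  if (is.null(names(results)) || any(!nzchar(names(results)))) {
    names(results) <- paste0("method", seq_along(results))
  }
  rows <- list()
  for (meth in names(results)) {
    df <- results[[meth]]
    if (is.null(df) || !nrow(df)) next
    padj <- if ("p_adjusted" %in% names(df)) df$p_adjusted else NA_real_
    sig <- is.na(padj) | padj < alpha
    df <- df[sig, , drop = FALSE]
    if (!nrow(df)) next
    rows[[meth]] <- data.frame(
      key = pair_key(df$snp1, df$snp2),
      snp1 = pmin(df$snp1, df$snp2), snp2 = pmax(df$snp1, df$snp2),
      method = meth,
      p_adjusted = if ("p_adjusted" %in% names(df)) df$p_adjusted
                   else NA_real_,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty_consensus(min_methods))
  all_rows <- do.call(rbind, rows)
  # one supporting vote per method per pair
  all_rows <- all_rows[!duplicated(paste(all_rows$key, all_rows$method)), ]
  out <- do.call(rbind, lapply(split(all_rows, all_rows$key), function(d) {
    data.frame(snp1 = d$snp1[1], snp2 = d$snp2[1],
               n_methods = nrow(d),
               methods = paste(sort(d$method), collapse = ","),
               min_p_adjusted = suppressWarnings(min(d$p_adjusted,
                                                     na.rm = TRUE)),
               stringsAsFactors = FALSE)
  }))
  out$min_p_adjusted[!is.finite(out$min_p_adjusted)] <- NA_real_
  out <- out[out$n_methods >= min_methods, , drop = FALSE]
  out <- out[order(out$min_p_adjusted, out$snp1, out$snp2), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "min_methods") <- min_methods
  class(out) <- c("consensus_report", "data.frame")
  out
}

empty_consensus <- function(min_methods) {
  out <- data.frame(snp1 = character(0), snp2 = character(0),
                    n_methods = integer(0), methods = character(0),
                    min_p_adjusted = numeric(0), stringsAsFactors = FALSE)
  attr(out, "min_methods") <- min_methods
  class(out) <- c("consensus_report", "data.frame")
  out
}

#' Replication of consensus pairs in an independent cohort
#'
#' Re-tests every discovery-consensus pair in a second cohort with the
#' requested methods. Closed-form methods (regression, fastepi, anova2)
#' are re-tested with the family-wise permutation adjustment restricted to
#' the pair's two variants; MDR/GMDR must first pass the cross-validation
#' consistency gate (`cvc >= cvc_min` out of `k_folds`) before their
#' permutation p is consulted. A pair replicates when at least one method
#' reaches permutation-adjusted p below `alpha` in the second cohort.
#' Pairs with a variant absent from the second cohort are reported as
#' `"untestable"`.
#'
#' @param discovery A `consensus_report` from [consensus_pairs()].
#' @param gm2 Second-cohort [genotype_matrix()].
#' @param pheno2 Second-cohort phenotype table.
#' @param methods Methods to re-test with (subset of `"regression"`,
#'   `"fastepi"`, `"anova2"`, `"mdr"`, `"gmdr"`).
#' @param B Permutations per method (default 1000).
#' @param alpha Replication significance level (default 0.05).
#' @param cvc_min CVC gate for MDR/GMDR (default 7).
#' @param k_folds Cross-validation folds for MDR/GMDR (default 10).
#' @param covariates Covariates for regression/GMDR paths.
#' @param seed Integer seed.
#' @return A data frame with one row per discovery pair: `snp1`, `snp2`,
#'   `status` (`"replicated"`, `"non-replicated"`, `"untestable"`),
#'   `best_method`, `best_p_adjusted`.
#' @export
replication_check <- function(discovery, gm2, pheno2,
                              methods = c("regression", "anova2"),
                              B = 1000, alpha = 0.05, cvc_min = 7,
                              k_folds = 10, covariates = NULL, seed = 1) {
  methods <- match.arg(methods,
                       c("regression", "fastepi", "anova2", "mdr", "gmdr"),
                       several.ok = TRUE)
  if (!nrow(discovery)) {
    warning("empty discovery consensus: nothing to replicate")
    return(data.frame(snp1 = character(0), snp2 = character(0),
                      status = character(0), best_method = character(0),
                      best_p_adjusted = numeric(0),
                      stringsAsFactors = FALSE))
  }
  present <- discovery$snp1 %in% gm2$variants$rsid &
    discovery$snp2 %in% gm2$variants$rsid
  if (!any(present)) {
    warning("no discovery pair has both variants in the second cohort")
  }
  out <- data.frame(snp1 = discovery$snp1, snp2 = discovery$snp2,
                    status = "untestable", best_method = NA_character_,
                    best_p_adjusted = NA_real_, stringsAsFactors = FALSE)
  closed <- intersect(methods, c("regression", "fastepi", "anova2"))
  cdr_modes <- intersect(methods, c("mdr", "gmdr"))
  cdr_cov <- if (is.null(covariates)) c("age", "sex") else covariates
  # CVC gate: the candidate pairs compete over the union of discovery loci
  # present in the second cohort, as in a fresh MDR run on that panel
  cvc_of <- list()
  if (length(cdr_modes) && any(present)) {
    loci <- unique(c(discovery$snp1[present], discovery$snp2[present]))
    gm_panel <- gm2[, loci]
    for (mode in cdr_modes) {
      panel_fit <- cdr_search(gm_panel, pheno2, mode = mode,
                              k_folds = k_folds, covariates = cdr_cov,
                              seed = seed)
      fp <- panel_fit$fold_pairs
      cvc_of[[mode]] <- table(pair_key(fp$snp1, fp$snp2))
    }
  }
  for (r in which(present)) {
    gm_pair <- gm2[, c(discovery$snp1[r], discovery$snp2[r])]
    best_p <- Inf; best_m <- NA_character_
    for (meth in closed) {
      scan_fn <- local({
        mm <- meth
        function(g, ph) pairwise_scan(g, ph, method = mm,
                                      covariates = covariates)
      })
      res <- permutation_adjust(scan_fn, gm_pair, pheno2, B = B,
                                seed = seed + r)
      p <- res$p_adjusted[1]
      if (!is.na(p) && p < best_p) { best_p <- p; best_m <- meth }
    }
    for (mode in cdr_modes) {
      key <- pair_key(discovery$snp1[r], discovery$snp2[r])
      cvc_pair <- if (key %in% names(cvc_of[[mode]]))
        as.integer(cvc_of[[mode]][key]) else 0L
      if (cvc_pair < cvc_min) next
      mod <- cdr_permutation(gm_pair, pheno2, mode = mode, B = B,
                             k_folds = k_folds, covariates = cdr_cov,
                             seed = seed + r)
      if (!is.na(mod$perm_p) && mod$perm_p < best_p) {
        best_p <- mod$perm_p; best_m <- mode
      }
    }
    out$status[r] <- if (is.finite(best_p) && best_p < alpha)
      "replicated" else "non-replicated"
    out$best_method[r] <- best_m
    out$best_p_adjusted[r] <- if (is.finite(best_p)) best_p else NA_real_
  }
  out
}
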