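#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test on the conditional distribution of the heterozygote
#' count given the allele counts: the p-value is the sum of the
#' probabilities of all heterozygote counts (of the correct parity) whose
#' conditional probability does not exceed that of the observed count. This
#' is the standard, non-mid-p definition. Probabilities are built by the
#' usual two-sided recurrence over heterozygote counts and normalised, so
#' the test is exact for any genotype counts that fit in double precision.
#'
#' @param n_hom_ref Count of homozygous-reference genotypes.
#' @param n_het Count of heterozygous genotypes.
#' @param n_hom_alt Count of homozygous-alternate genotypes.
#' @return The exact two-sided p-value in `(0, 1]`.
#' @examples
#' hwe_exact_test(100, 0, 0)   # monomorphic: 1
#' hwe_exact_test(10, 10, 10)
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  counts <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("genotype counts must be non-negative integers")
  }
  n <- sum(counts)
  if (n == 0) stop("all genotype counts are zero")
  n_rare <- 2 * min(n_hom_ref, n_hom_alt) + n_het
  if (n_rare == 0 || n_rare == 2 * n) return(1)  # monomorphic
  # heterozygote counts share the parity of the rare-allele count
  h_vals <- seq(n_rare %% 2, min(n_rare, 2 * n - n_rare), by = 2)
  probs <- numeric(length(h_vals))
  # start from the largest valid het count and recurse downward:
  # P(h-2)/P(h) = h*(h-1) / (4*(hr+1)*(hc+1)) with hr, hc the two
  # homozygote counts implied by h
  i0 <- length(h_vals)
  probs[i0] <- 1
  for (i in seq(i0, 2, length.out = max(0, i0 - 1))) {
    h <- h_vals[i]
    hom_r <- (n_rare - h) / 2
    hom_c <- n - h - hom_r
    probs[i - 1] <- probs[i] * h * (h - 1) /
      (4 * (hom_r + 1) * (hom_c + 1))
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_het, h_vals)]
  if (is.na(p_obs)) stop("heterozygote count has wrong parity for totals")
  min(1, sum(probs[probs <= p_obs * (1 + 1e-9)]))
}

#' Quality-control configuration
#'
#' Defaults follow common imputation-aware variant QC for association
#' panels: Hardy-Weinberg exact p > 1e-6, call rate > 99%, imputation
#' r^2 >= 0.7 (applied only when an r^2 is recorded), biallelic sites only,
#' stratum allele-frequency bias flagged at BH-adjusted p < 0.01, locus
#' pruning within 500 kb, and single-SNP association p <= 1e-4 for locus
#' selection. Discovery-style strictness (no missing genotypes at all)
#' corresponds to `min_call_rate = 1`.
#'
#' @param hwe_p_min Exclusion threshold: variants with HWE exact p <= this
#'   value are removed.
#' @param min_call_rate Minimum fraction of non-missing calls.
#' @param min_info_r2 Minimum imputation r^2 when recorded.
#' @param require_biallelic Drop variants whose alleles are not a single
#'   REF/ALT pair.
#' @param stratum_bias_alpha BH-adjusted significance level for the stratum
#'   allele-frequency bias test.
#' @param prune_window_bp Distance window for [prune_by_distance()].
#' @param assoc_p_max Single-SNP association p-value cap for locus selection.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(hwe_p_min = 1e-6, min_call_rate = 0.99,
                      min_info_r2 = 0.7, require_biallelic = TRUE,
                      stratum_bias_alpha = 0.01,
                      prune_window_bp = 500000L, assoc_p_max = 1e-4) {
  stopifnot(hwe_p_min > 0, hwe_p_min < 1,
            min_call_rate > 0, min_call_rate <= 1,
            min_info_r2 >= 0, min_info_r2 <= 1,
            stratum_bias_alpha > 0, stratum_bias_alpha < 1,
            prune_window_bp > 0,
            assoc_p_max > 0, assoc_p_max <= 1)
  structure(list(hwe_p_min = hwe_p_min, min_call_rate = min_call_rate,
                 min_info_r2 = min_info_r2,
                 require_biallelic = require_biallelic,
                 stratum_bias_alpha = stratum_bias_alpha,
                 prune_window_bp = as.integer(prune_window_bp),
                 assoc_p_max = assoc_p_max),
            class = "qc_config")
}

#' Variant-level quality control
#'
#' Applies, in order: biallelic check, call-rate filter, Hardy-Weinberg
#' exact test, and imputation-r^2 filter (only where an r^2 is recorded).
#' The report records, per variant, the computed metrics, a pass flag and
#' the first failed filter as a reason code, plus before/after counts per
#' filter stage.
#'
#' @param gm A [genotype_matrix()].
#' @param cfg A [qc_config()].
#' @return A list with the filtered `gm` and a `report` data frame
#'   (attribute `counts` holds the per-stage retention counts).
#' @export
filter_variants <- function(gm, cfg = qc_config()) {
  if (n_variants(gm) == 0) stop("empty genotype matrix")
  m <- n_variants(gm)
  calls <- gm$calls
  v <- gm$variants
  call_rate <- colMeans(!is.na(calls))
  hwe_p <- vapply(seq_len(m), function(j) {
    g <- calls[, j]
    g <- g[!is.na(g)]
    if (!length(g)) return(NA_real_)
    hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2))
  }, numeric(1))
  maf <- vapply(seq_len(m), function(j) {
    g <- calls[, j]
    g <- g[!is.na(g)]
    if (!length(g)) return(NA_real_)
    af <- mean(g) / 2
    min(af, 1 - af)
  }, numeric(1))
  biallelic <- !grepl(",", v$alt) & nchar(v$ref) >= 1 & nchar(v$alt) >= 1 &
    v$ref != v$alt
  reason <- rep(NA_character_, m)
  if (cfg$require_biallelic) reason[!biallelic] <- "biallelic"
  sel <- is.na(reason) & call_rate < cfg$min_call_rate
  reason[sel] <- "call_rate"
  sel <- is.na(reason) & (!is.na(hwe_p) & hwe_p <= cfg$hwe_p_min)
  reason[sel] <- "hwe"
  sel <- is.na(reason) & !is.na(v$info_r2) & v$info_r2 < cfg$min_info_r2
  reason[sel] <- "info_r2"
  pass <- is.na(reason)
  report <- data.frame(rsid = v$rsid, call_rate = call_rate,
                       hwe_p = hwe_p, maf = maf,
                       info_r2 = v$info_r2, pass = pass,
                       reason = reason, stringsAsFactors = FALSE)
  stage <- c("biallelic", "call_rate", "hwe", "info_r2")
  counts <- c(input = m,
              stats::setNames(vapply(seq_along(stage), function(k) {
                m - sum(reason %in% stage[seq_len(k)])
              }, numeric(1)), stage))
  attr(report, "counts") <- counts
  list(gm = gm[, which(pass)], report = report)
}

#' Greedy distance-based locus pruning
#'
#' Orders loci by ascending association p-value and retains each locus only
#' if no already-retained locus lies on the same chromosome within
#' `window_bp` (inclusive). This keeps the most significant SNP among any
#' cluster of loci within the window (500 kb by default). Duplicate
#' (chrom, pos) entries keep the smaller p-value with a warning.
#'
#' @param variants Data frame with columns `rsid`, `chrom`, `pos` and
#'   `assoc_p`.
#' @param window_bp Window in base pairs (default 500000).
#' @return The retained subset of `variants`, in input order.
#' @export
prune_by_distance <- function(variants, window_bp = 500000L) {
  stopifnot(all(c("rsid", "chrom", "pos", "assoc_p") %in% names(variants)))
  if (any(variants$assoc_p <= 0 | variants$assoc_p > 1)) {
    stop("assoc_p must lie in (0, 1]")
  }
  v <- variants
  key <- paste(v$chrom, v$pos)
  if (anyDuplicated(key)) {
    warning("duplicate (chrom, pos) entries: keeping the smaller assoc_p")
    keep_dup <- !logical(nrow(v))
    for (k in unique(key[duplicated(key)])) {
      idx <- which(key == k)
      keep_dup[idx] <- FALSE
      keep_dup[idx[which.min(v$assoc_p[idx])]] <- TRUE
    }
    v <- v[keep_dup, , drop = FALSE]
  }
  ord <- order(v$assoc_p, v$chrom, v$pos)
  retained <- integer(0)
  for (i in ord) {
    same <- retained[v$chrom[retained] == v$chrom[i]]
    if (!length(same) || all(abs(v$pos[same] - v$pos[i]) > window_bp)) {
      retained <- c(retained, i)
    }
  }
  v[sort(retained), , drop = FALSE]
}

#' Stratum allele-frequency bias test
#'
#' Guards against confounding of the phenotype classes by an unrelated
#' stratifying variable (for instance clinical diagnosis groups): for every
#' variant and every pair of strata, a 2x2 allele-count Fisher exact test
#' compares ALT/REF allele counts; the minimum pairwise p per variant is
#' Benjamini-Hochberg adjusted across variants, and variants below `alpha`
#' are flagged for removal.
#'
#' @param gm A [genotype_matrix()].
#' @param strata Character or factor vector of per-sample stratum labels,
#'   aligned with the rows of `gm`.
#' @param alpha BH-adjusted flagging threshold (default 0.01).
#' @return A data frame with per-variant `p_min`, `p_adj` and `flagged`;
#'   attribute `excluded` lists the flagged rsids.
#' @export
stratum_af_bias_test <- function(gm, strata, alpha = 0.01) {
  strata <- as.character(strata)
  if (length(strata) != n_samples(gm)) {
    stop("strata must have one label per sample")
  }
  levs <- unique(strata)
  if (length(levs) < 2) stop("need >=2 strata")
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  m <- n_variants(gm)
  p_min <- rep(NA_real_, m)
  for (j in seq_len(m)) {
    g <- gm$calls[, j]
    best <- NA_real_
    for (pr in pairs) {
      tab <- matrix(NA_real_, 2, 2)
      skip <- FALSE
      for (k in 1:2) {
        gs <- g[strata == pr[k] & !is.na(g)]
        if (!length(gs)) { skip <- TRUE; break }
        alt <- sum(gs)
        tab[k, ] <- c(alt, 2 * length(gs) - alt)
      }
      if (skip) next
      p <- stats::fisher.test(tab)$p.value
      if (is.na(best) || p < best) best <- p
    }
    p_min[j] <- best
  }
  p_adj <- stats::p.adjust(p_min, method = "BH")
  flagged <- !is.na(p_adj) & p_adj < alpha
  out <- data.frame(rsid = gm$variants$rsid, p_min = p_min,
                    p_adj = p_adj, flagged = flagged,
                    stringsAsFactors = FALSE)
  attr(out, "excluded") <- out$rsid[flagged]
  out
}
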