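#' Genotype-combination counts by BMI class
#'
#' Cross-tabulates the nine joint-genotype combinations of a variant pair
#' against the high/low BMI classes. Rows index the first locus's ALT
#' count (0, 1, 2) and columns the second's; cells can be relabelled to
#' effect-allele orientation at reporting time without recoding calls.
#'
#' @param gA,gB Integer genotype vectors in `{0, 1, 2}`.
#' @param bmi_class `"high"`/`"low"` labels (or logical, `TRUE` = high).
#' @return An object of class `combination_table`: 3x3 integer matrices
#'   `high` and `low`, and totals `n_high`, `n_low`.
#' @export
combination_counts <- function(gA, gB, bmi_class) {
  if (is.logical(bmi_class)) bmi_class <- ifelse(bmi_class, "high", "low")
  keep <- !is.na(gA) & !is.na(gB) & !is.na(bmi_class)
  gA <- gA[keep]; gB <- gB[keep]; bmi_class <- bmi_class[keep]
  count_grid <- function(idx) {
    tab <- matrix(tabulate(cell_index(gA[idx], gB[idx]), nbins = 9L),
                  nrow = 3, byrow = TRUE,
                  dimnames = list(gA = 0:2, gB = 0:2))
    storage.mode(tab) <- "integer"
    tab
  }
  structure(list(high = count_grid(bmi_class == "high"),
                 low = count_grid(bmi_class == "low"),
                 n_high = sum(bmi_class == "high"),
                 n_low = sum(bmi_class == "low")),
            class = "combination_table")
}

#' @export
print.combination_table <- function(x, ...) {
  cat(sprintf("genotype combinations: %d high-BMI, %d low-BMI samples\n",
              x$n_high, x$n_low))
  cat("high-BMI counts:\n"); print(x$high)
  cat("low-BMI counts:\n"); print(x$low)
  if (!is.null(x$z)) {
    cat("direction (p < alpha):\n"); print(x$direction)
  }
  invisible(x)
}

#' Two-sample z test for proportions
#'
#' Pooled-variance two-sample z test of `x1/n1` against `x2/n2` with a
#' two-sided normal p-value. Degenerate pooled proportions (0 or 1) return
#' `z = 0, p = 1`.
#'
#' @param x1,n1 Successes and trials in the first sample.
#' @param x2,n2 Successes and trials in the second sample.
#' @return A list with `z` and `p`.
#' @export
proportion_z_test <- function(x1, n1, x2, n2) {
  stopifnot(n1 > 0, n2 > 0, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  p1 <- x1 / n1; p2 <- x2 / n2
  pooled <- (x1 + x2) / (n1 + n2)
  if (pooled <= 0 || pooled >= 1) return(list(z = 0, p = 1))
  se <- sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  z <- (p1 - p2) / se
  list(z = z, p = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
}

#' Per-cell enrichment of genotype combinations
#'
#' For each of the nine genotype combinations, compares the cell's
#' prevalence in the high-BMI group (`count/n_high`) with its prevalence in
#' the low-BMI group (`count/n_low`) by [proportion_z_test()], and assigns
#' a direction when the two-sided p falls below `alpha`: `enriched_high`
#' when the high-BMI proportion is larger, `enriched_low` otherwise. Cells
#' are tested at the raw `alpha` by default; `bh_adjust = TRUE` applies a
#' Benjamini-Hochberg correction across the nine cells first.
#'
#' @param tab A `combination_table` from [combination_counts()].
#' @param alpha Per-cell significance level (default 0.05).
#' @param bh_adjust Apply BH across the 9 cells (default `FALSE`).
#' @return The `combination_table` with 3x3 matrices `z`, `p` and
#'   character `direction` (`"enriched_high"`, `"enriched_low"`, `"none"`)
#'   added.
#' @export
combination_enrichment <- function(tab, alpha = 0.05, bh_adjust = FALSE) {
  stopifnot(inherits(tab, "combination_table"))
  if (tab$n_high <= 0 || tab$n_low <= 0) {
    stop("both BMI classes must be non-empty")
  }
  z <- p <- matrix(NA_real_, 3, 3, dimnames = dimnames(tab$high))
  for (i in 1:3) {
    for (j in 1:3) {
      zt <- proportion_z_test(tab$high[i, j], tab$n_high,
                              tab$low[i, j], tab$n_low)
      z[i, j] <- zt$z; p[i, j] <- zt$p
    }
  }
  p_gate <- if (bh_adjust) {
    matrix(stats::p.adjust(as.vector(p), method = "BH"), 3, 3,
           dimnames = dimnames(p))
  } else p
  direction <- matrix("none", 3, 3, dimnames = dimnames(p))
  sig <- p_gate < alpha
  direction[sig & z > 0] <- "enriched_high"
  direction[sig & z < 0] <- "enriched_low"
  tab$z <- z; tab$p <- p; tab$direction <- direction
  tab$alpha <- alpha
  tab
}

#' One-sided binomial test for carrier enrichment
#'
#' Upper-tail binomial probability of observing at least `k_low` low-BMI
#' individuals among `n_carriers` carriers of a genotype combination, under
#' a baseline low-BMI proportion `p0` (typically the cohort-wide low-BMI
#' fraction).
#'
#' @param k_low Low-BMI carriers observed.
#' @param n_carriers Total carriers.
#' @param p0 Baseline low-BMI proportion, in `(0, 1)`.
#' @return The one-sided p-value `P[X >= k_low]`.
#' @export
carrier_binomial_test <- function(k_low, n_carriers, p0) {
  stopifnot(k_low >= 0, k_low <= n_carriers)
  if (!is.finite(p0) || p0 <= 0 || p0 >= 1) {
    stop("baseline proportion p0 must lie in (0, 1)")
  }
  stats::pbinom(k_low - 1, size = n_carriers, prob = p0,
                lower.tail = FALSE)
}
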