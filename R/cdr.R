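# Joint-genotype cell index in 1..9 (gA major), NA-propagating.
cell_index <- function(gA, gB) 3L * gA + gB + 1L

# Internal integer label codes: 1 high, 0 low, NA unclassifiable.
label_codes_to_char <- function(codes) {
  out <- matrix(ifelse(is.na(codes), "unclassifiable",
                       ifelse(codes == 1L, "high", "low")),
                nrow = 3, ncol = 3, byrow = TRUE,
                dimnames = list(gA = 0:2, gB = 0:2))
  out
}

# MDR labels, exact integer tie rule: a cell is high-risk iff
# cases*n_controls >= controls*n_cases (ratio >= overall ratio, ties high).
mdr_labels_int <- function(cells, status, train) {
  cases <- tabulate(cells[train & status], nbins = 9L)
  controls <- tabulate(cells[train & !status], nbins = 9L)
  n_case <- sum(cases); n_ctrl <- sum(controls)
  if (n_case == 0 || n_ctrl == 0) stop("one-class training set")
  codes <- as.integer(cases * n_ctrl >= controls * n_case)
  codes[cases + controls == 0] <- NA_integer_
  codes
}

# GMDR labels: cell score sum >= 0 -> high. Scores are re-centred on the
# training subset so the labelling never sees held-out samples; with a
# binomial family and no covariates this reduces exactly to the MDR
# training case:control ratio rule. A small tolerance resolves floating
# ties to high-risk, matching MDR's tie convention.
gmdr_labels_int <- function(cells, scores, train) {
  cnt <- tabulate(cells[train], nbins = 9L)
  s_tr <- scores[train] - mean(scores[train])
  sums <- numeric(9)
  agg <- rowsum(s_tr, group = cells[train])
  sums[as.integer(rownames(agg))] <- agg[, 1]
  tol <- 1e-9 * max(1, max(abs(scores)))
  codes <- as.integer(sums >= -tol)
  codes[cnt == 0] <- NA_integer_
  codes
}

# Balanced accuracy of integer labels on an evaluation subset; samples in
# unclassifiable cells are excluded. Returns NA when nothing is
# classifiable, 0.5 when only one class remains classifiable.
ba_eval <- function(codes, cells, status, eval_idx) {
  pred <- codes[cells[eval_idx]]
  st <- status[eval_idx]
  ok <- !is.na(pred)
  if (!any(ok)) return(NA_real_)
  pred <- pred[ok]; st <- st[ok]
  n_case <- sum(st); n_ctrl <- sum(!st)
  if (n_case == 0 || n_ctrl == 0) return(0.5)
  sens <- sum(pred == 1L & st) / n_case
  spec <- sum(pred == 0L & !st) / n_ctrl
  (sens + spec) / 2
}

#' MDR high/low risk labels for the 3x3 joint-genotype grid
#'
#' Labels each joint-genotype cell high-risk when its training
#' case:control ratio is at least the overall training ratio (ties count as
#' high-risk; a cell with cases but no controls is high-risk; an empty cell
#' is unclassifiable). This is the dimensionality-reduction step of MDR:
#' the 3x3 genotype grid collapses to a binary classifier.
#'
#' @param gA,gB Integer genotype vectors in `{0, 1, 2}`.
#' @param bmi_class `"high"`/`"low"` labels (or logical, `TRUE` = case).
#' @param train_index Indices (or logical mask) of the training samples;
#'   defaults to all samples.
#' @return A 3x3 character matrix (rows `gA` = 0,1,2; columns `gB`) with
#'   entries `"high"`, `"low"` or `"unclassifiable"`.
#' @export
mdr_cell_labels <- function(gA, gB, bmi_class,
                            train_index = seq_along(gA)) {
  status <- if (is.logical(bmi_class)) bmi_class else bmi_class == "high"
  train <- logical(length(gA))
  train[train_index] <- TRUE
  train <- train & !is.na(gA) & !is.na(gB) & !is.na(status)
  cells <- cell_index(gA, gB)
  label_codes_to_char(mdr_labels_int(cells, status, train))
}

#' Balanced accuracy of a risk map
#'
#' Classifies evaluation samples by their cell's risk label (high-risk
#' predicts case) and returns `(sensitivity + specificity) / 2`. Samples in
#' unclassifiable cells are excluded from both terms, which keeps the null
#' expectation at 0.5.
#'
#' @param risk_map 3x3 character matrix from [mdr_cell_labels()].
#' @param gA,gB Integer genotype vectors.
#' @param bmi_class `"high"`/`"low"` labels (or logical, `TRUE` = case).
#' @param eval_index Indices of the evaluation samples (default all).
#' @return Balanced accuracy in `[0, 1]`.
#' @export
balanced_accuracy <- function(risk_map, gA, gB, bmi_class,
                              eval_index = seq_along(gA)) {
  status <- if (is.logical(bmi_class)) bmi_class else bmi_class == "high"
  codes <- as.integer(t(risk_map == "high"))
  codes[t(risk_map) == "unclassifiable"] <- NA_integer_
  cells <- cell_index(gA, gB)
  ba <- ba_eval(codes, cells, status, eval_index)
  if (is.na(ba)) stop("all evaluation samples fall in unclassifiable cells")
  ba
}

#' GMDR score statistics from a covariate-only GLM
#'
#' Fits the covariate-only generalized linear model (identity link for
#' `"gaussian"` on BMI, logit for `"binomial"` on the BMI class) and
#' returns the response-scale residuals `y - fitted`. These per-sample
#' scores replace case/control counts in the GMDR cell-labelling rule,
#' which lets the MDR machinery handle quantitative phenotypes and
#' covariates. With an intercept the scores sum to zero.
#'
#' @param pheno A phenotype table with `bmi`, `bmi_class` and any covariate
#'   columns.
#' @param covariates Character vector of covariate column names (`NULL` for
#'   an intercept-only model).
#' @param family `"gaussian"` or `"binomial"`.
#' @return Numeric score vector, one per phenotype row.
#' @export
gmdr_scores <- function(pheno, covariates = c("age", "sex"),
                        family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  y <- if (family == "gaussian") pheno$bmi
       else as.integer(pheno$bmi_class == "high")
  if (is.null(covariates) || !length(covariates)) {
    fam <- if (family == "gaussian") stats::gaussian() else stats::binomial()
    fit <- stats::glm(y ~ 1, family = fam)
  } else {
    missing_cv <- setdiff(covariates, names(pheno))
    if (length(missing_cv)) stop("unknown covariate: ", missing_cv[1])
    X <- stats::model.matrix(
      ~ ., data = as.data.frame(pheno[, covariates, drop = FALSE]))
    if (qr(X)$rank < ncol(X)) stop("rank-deficient covariate matrix")
    dat <- data.frame(y = y, pheno[, covariates, drop = FALSE])
    fam <- if (family == "gaussian") stats::gaussian() else stats::binomial()
    fit <- stats::glm(y ~ ., data = dat, family = fam)
  }
  as.numeric(y - stats::fitted(fit))
}

# Precompute the joint-genotype cell index for every variant pair.
pair_cells <- function(calls) {
  m <- ncol(calls)
  if (m < 2) stop("need at least 2 variants")
  pair_idx <- utils::combn(m, 2)
  cells <- matrix(0L, nrow(calls), ncol(pair_idx))
  for (k in seq_len(ncol(pair_idx))) {
    cells[, k] <- cell_index(calls[, pair_idx[1, k]],
                             calls[, pair_idx[2, k]])
  }
  list(pair_idx = pair_idx, cells = cells)
}

# Balanced accuracy from 9-cell case/control count vectors (columns =
# folds): samples in unlabelled (NA) cells are excluded; one-class or
# fully unclassifiable folds score the uninformative 0.5.
ba_from_counts <- function(case_cnt, ctrl_cnt, high, na) {
  ok <- !na
  den_case <- colSums(case_cnt * ok)
  den_ctrl <- colSums(ctrl_cnt * ok)
  sens <- colSums(case_cnt * (ok & high)) / den_case
  spec <- colSums(ctrl_cnt * (ok & !high)) / den_ctrl
  ba <- (sens + spec) / 2
  ba[den_case == 0 | den_ctrl == 0] <- 0.5
  ba
}

# Internal engine shared by cdr_search and cdr_permutation: runs the
# k-fold pair competition over precomputed pair cell indices. All
# training-fold counts are derived as totals minus the held-out fold's
# counts, so each pair costs two tabulate passes over the samples.
cdr_engine <- function(pc, status, scores, mode, k_folds, seed) {
  n <- nrow(pc$cells)
  n_pairs <- ncol(pc$cells)
  if (n < k_folds) stop("fewer samples than folds")
  # stratified fold assignment: by class (mdr) or score sign (gmdr)
  strata <- if (mode == "mdr") status else scores > 0
  folds <- integer(n)
  with_seed(seed, {
    for (s in unique(strata)) {
      idx <- which(strata == s)
      folds[idx] <- sample(rep(seq_len(k_folds), length.out = length(idx)))
    }
  })
  comp_base <- 9L * (folds - 1L)
  nb <- 9L * k_folds
  pos <- if (mode == "mdr") status else scores > 0
  idx_pos <- which(pos)
  idx_neg <- which(!pos)
  if (mode == "mdr" && (!length(idx_pos) || !length(idx_neg))) {
    stop("one-class training set")
  }
  tol <- if (mode == "gmdr") 1e-9 * max(1, max(abs(scores))) else 0
  train_ba <- matrix(NA_real_, n_pairs, k_folds)
  test_ba <- matrix(NA_real_, n_pairs, k_folds)
  for (k in seq_len(n_pairs)) {
    comp <- pc$cells[, k] + comp_base
    case_f <- matrix(tabulate(comp[idx_pos], nbins = nb), 9L, k_folds)
    ctrl_f <- matrix(tabulate(comp[idx_neg], nbins = nb), 9L, k_folds)
    case_tr <- rowSums(case_f) - case_f
    ctrl_tr <- rowSums(ctrl_f) - ctrl_f
    cnt_tr <- case_tr + ctrl_tr
    na_tr <- cnt_tr == 0
    if (mode == "mdr") {
      n_case_tr <- rep(colSums(case_tr), each = 9L)
      n_ctrl_tr <- rep(colSums(ctrl_tr), each = 9L)
      high <- case_tr * n_ctrl_tr >= ctrl_tr * n_case_tr
    } else {
      sum_f <- matrix(0, nb, 1)
      agg <- rowsum(scores, comp)
      sum_f[as.integer(rownames(agg)), 1] <- agg[, 1]
      sum_f <- matrix(sum_f, 9L, k_folds)
      sum_tr <- rowSums(sum_f) - sum_f
      mean_tr <- rep(colSums(sum_tr) / colSums(cnt_tr), each = 9L)
      high <- (sum_tr - cnt_tr * mean_tr) >= -tol
    }
    train_ba[k, ] <- ba_from_counts(case_tr, ctrl_tr, high, na_tr)
    test_ba[k, ] <- ba_from_counts(case_f, ctrl_f, high, na_tr)
  }
  chosen <- apply(train_ba, 2, which.max)  # first max = canonical ties
  tab <- tabulate(chosen, nbins = n_pairs)
  cvc <- max(tab)
  cand <- which(tab == cvc)
  if (length(cand) > 1) {
    mean_te <- rowMeans(test_ba)[cand]
    cand <- cand[order(-mean_te, cand)]
  }
  best <- cand[1]
  list(best = best, pair_idx = pc$pair_idx, cvc = cvc, chosen = chosen,
       train_ba = mean(train_ba[best, ]), test_ba = mean(test_ba[best, ]),
       cells_best = pc$cells[, best], folds = folds)
}

#' MDR / GMDR search over variant pairs with cross-validation
#'
#' Runs the constructive-induction search of MDR (or its generalized
#' score-based form) over all variant pairs: a stratified k-fold split is
#' drawn, within each fold the pair with the best training balanced
#' accuracy is selected, and the pair chosen most often is reported. The
#' cross-validation consistency (CVC) is the number of folds selecting that
#' modal pair; training and testing balanced accuracies are averaged over
#' folds. Ties on CVC break to the higher mean testing balanced accuracy,
#' then to canonical (chrom, pos) pair order.
#'
#' @param gm A [genotype_matrix()] (QC-passed, no missing calls).
#' @param pheno A phenotype table sharing sample ids with `gm`.
#' @param mode `"mdr"` (binary BMI class) or `"gmdr"` (score statistics
#'   from a covariate GLM).
#' @param k_folds Number of cross-validation folds (default 10).
#' @param covariates GMDR covariate columns (default `c("age", "sex")`;
#'   ignored for MDR).
#' @param family GMDR GLM family (default `"gaussian"`).
#' @param seed Integer seed for the fold split.
#' @return An object of class `cdr_model`: `pair`, `cvc`, `train_ba`,
#'   `test_ba`, `risk_map` (trained on the full data), `k_folds`, `mode`;
#'   permutation fields are filled by [cdr_permutation()].
#' @export
cdr_search <- function(gm, pheno, mode = c("mdr", "gmdr"), k_folds = 10,
                       covariates = c("age", "sex"),
                       family = c("gaussian", "binomial"), seed = 1) {
  mode <- match.arg(mode)
  family <- match.arg(family)
  al <- align_samples(gm, pheno)
  gm <- al$gm; pheno <- al$pheno
  ord <- canonical_variant_order(gm$variants)
  gm <- gm[, ord]
  status <- pheno$bmi_class == "high"
  scores <- NULL
  if (mode == "mdr") {
    if (!any(status) || !any(!status)) stop("need both BMI classes for MDR")
  } else {
    scores <- gmdr_scores(pheno, covariates, family)
    status <- scores > 0  # classification target in score space
  }
  eng <- cdr_engine(pair_cells(gm$calls), status, scores, mode, k_folds,
                    seed)
  i <- eng$pair_idx[1, eng$best]; j <- eng$pair_idx[2, eng$best]
  fold_pairs <- data.frame(
    fold = seq_len(k_folds),
    snp1 = gm$variants$rsid[eng$pair_idx[1, eng$chosen]],
    snp2 = gm$variants$rsid[eng$pair_idx[2, eng$chosen]],
    stringsAsFactors = FALSE)
  codes_full <- if (mode == "mdr") {
    mdr_labels_int(eng$cells_best, status, rep(TRUE, length(status)))
  } else {
    gmdr_labels_int(eng$cells_best, scores, rep(TRUE, length(scores)))
  }
  structure(list(pair = c(gm$variants$rsid[i], gm$variants$rsid[j]),
                 cvc = eng$cvc, k_folds = k_folds,
                 train_ba = eng$train_ba, test_ba = eng$test_ba,
                 risk_map = label_codes_to_char(codes_full),
                 fold_pairs = fold_pairs,
                 mode = mode, seed = seed,
                 perm_cutoff_05 = NA_real_, perm_cutoff_01 = NA_real_,
                 perm_p = NA_real_),
            class = "cdr_model")
}

#' @export
print.cdr_model <- function(x, ...) {
  cat(sprintf("%s model: %s x %s\n", toupper(x$mode),
              x$pair[1], x$pair[2]))
  cat(sprintf("  CVC %d/%d, training BA %.4f, testing BA %.4f\n",
              x$cvc, x$k_folds, x$train_ba, x$test_ba))
  if (!is.na(x$perm_p)) {
    cat(sprintf("  permutation p %.4g (cutoff TBA %.4f at 0.05, %.4f at 0.01)\n",
                x$perm_p, x$perm_cutoff_05, x$perm_cutoff_01))
  }
  invisible(x)
}

#' Permutation significance for an MDR/GMDR model
#'
#' Builds the null distribution of the best testing balanced accuracy by
#' permuting the phenotype rows (with their covariates, preserving the
#' covariate-phenotype relationship) against the genotype rows and
#' re-running the full [cdr_search()] each time. Cutoffs are the
#' `1 - alpha` empirical quantiles of the null; the permutation p-value is
#' `(1 + #[null >= observed]) / (1 + B)`.
#'
#' @inheritParams cdr_search
#' @param B Number of permutations (`>= 19`).
#' @param alpha_list Significance levels for cutoff reporting.
#' @return The observed `cdr_model` with `perm_cutoff_*` and `perm_p`
#'   filled; the null distribution is attached as attribute `"null_tba"`.
#' @export
cdr_permutation <- function(gm, pheno, mode = c("mdr", "gmdr"), B = 1000,
                            alpha_list = c(0.05, 0.01), k_folds = 10,
                            covariates = c("age", "sex"),
                            family = c("gaussian", "binomial"), seed = 1) {
  mode <- match.arg(mode)
  family <- match.arg(family)
  if (B < 19) stop("need B >= 19 permutations")
  observed <- cdr_search(gm, pheno, mode, k_folds, covariates, family,
                         seed)
  # permuting the phenotype rows together with their covariates permutes
  # the per-sample class labels and GLM scores as vectors, so the null
  # searches reuse the aligned genotype cells directly
  al <- align_samples(gm, pheno)
  gm_al <- al$gm[, canonical_variant_order(al$gm$variants)]
  pheno_al <- al$pheno
  status <- pheno_al$bmi_class == "high"
  scores <- NULL
  if (mode == "gmdr") {
    scores <- gmdr_scores(pheno_al, covariates, family)
    status <- scores > 0
  }
  pc <- pair_cells(gm_al$calls)
  n <- nrow(pheno_al)
  null_tba <- numeric(B)
  perms <- with_seed(seed,
                     lapply(seq_len(B), function(b) sample.int(n)))
  for (b in seq_len(B)) {
    pm <- perms[[b]]
    null_tba[b] <- cdr_engine(pc, status[pm],
                              if (is.null(scores)) NULL else scores[pm],
                              mode, k_folds, seed + b)$test_ba
  }
  cutoffs <- stats::quantile(null_tba, probs = 1 - alpha_list, type = 1,
                             names = FALSE)
  names(cutoffs) <- paste0("alpha_", alpha_list)
  observed$perm_cutoff_05 <- unname(cutoffs[which(alpha_list == 0.05)[1]])
  observed$perm_cutoff_01 <- unname(cutoffs[which(alpha_list == 0.01)[1]])
  observed$perm_p <- (1 + sum(null_tba >= observed$test_ba)) / (1 + B)
  observed$cutoffs <- cutoffs
  attr(observed, "null_tba") <- null_tba
  observed
}

#' Serialize / read a fitted MDR-family model
#'
#' Flat key-value text format: pair, CVC, accuracies, permutation cutoffs
#' and p, and the nine cell labels (`cell_<gA><gB>`).
#'
#' @param model A `cdr_model`.
#' @param path File path.
#' @return `write_cdr_model` invisibly returns `path`; `read_cdr_model`
#'   returns the reconstructed `cdr_model`.
#' @export
write_cdr_model <- function(model, path) {
  kv <- c(snp1 = model$pair[1], snp2 = model$pair[2],
          mode = model$mode, cvc = model$cvc, k_folds = model$k_folds,
          train_ba = sprintf("%.15g", model$train_ba),
          test_ba = sprintf("%.15g", model$test_ba),
          perm_cutoff_05 = sprintf("%.15g", model$perm_cutoff_05),
          perm_cutoff_01 = sprintf("%.15g", model$perm_cutoff_01),
          perm_p = sprintf("%.15g", model$perm_p))
  cells <- as.vector(t(model$risk_map))
  names(cells) <- paste0("cell_", rep(0:2, each = 3), rep(0:2, 3))
  kv <- c(kv, cells)
  writeLines(paste(names(kv), kv, sep = "\t"), path)
  invisible(path)
}

#' @rdname write_cdr_model
#' @export
read_cdr_model <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  kv <- stats::setNames(vapply(parts, `[`, character(1), 2),
                        vapply(parts, `[`, character(1), 1))
  risk <- matrix(kv[paste0("cell_", rep(0:2, each = 3), rep(0:2, 3))],
                 nrow = 3, byrow = TRUE, dimnames = list(gA = 0:2, gB = 0:2))
  num <- function(x) if (identical(unname(x), "NA")) NA_real_
                     else as.numeric(x)
  structure(list(pair = unname(kv[c("snp1", "snp2")]),
                 cvc = as.integer(kv["cvc"]),
                 k_folds = as.integer(kv["k_folds"]),
                 train_ba = num(kv["train_ba"]),
                 test_ba = num(kv["test_ba"]),
                 risk_map = risk, mode = unname(kv["mode"]),
                 seed = NA_integer_,
                 perm_cutoff_05 = num(kv["perm_cutoff_05"]),
                 perm_cutoff_01 = num(kv["perm_cutoff_01"]),
                 perm_p = num(kv["perm_p"])),
            class = "cdr_model")
}
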