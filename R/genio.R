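#' Construct a genotype matrix object
#'
#' Couples a samples-by-variants matrix of additive-coded hard calls with its
#' variant metadata. Calls count copies of the ALT allele: 0 homozygous
#' reference, 1 heterozygous, 2 homozygous alternate; `NA` marks a missing
#' call. Effect-allele orientation is a reporting-layer relabel and never
#' changes the stored coding.
#'
#' @param calls Integer matrix, samples in rows and variants in columns,
#'   values in `{0, 1, 2, NA}`. Row names are sample ids; column names, when
#'   present, must match `variants$rsid`.
#' @param variants Data frame with columns `rsid`, `chrom`, `pos` (1-based),
#'   `ref`, `alt`, and optionally `info_r2` (imputation quality in `[0, 1]`).
#' @return An object of class `genotype_matrix` with elements `calls` and
#'   `variants`.
#' @examples
#' calls <- matrix(c(0L, 1L, 2L, 1L, 0L, 2L), nrow = 3,
#'                 dimnames = list(c("s1", "s2", "s3"), c("rs1", "rs2")))
#' vars <- data.frame(rsid = c("rs1", "rs2"), chrom = c("1", "1"),
#'                    pos = c(100L, 2000L), ref = c("A", "C"),
#'                    alt = c("G", "T"))
#' gm <- genotype_matrix(calls, vars)
#' @export
genotype_matrix <- function(calls, variants) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  bad <- !is.na(calls) & !(calls %in% 0:2)
  if (any(bad)) {
    stop("genotype calls must be 0, 1, 2 or NA; found ", calls[bad][1])
  }
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  required <- c("rsid", "chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(required, names(variants))
  if (length(missing_cols)) {
    stop("variant table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!("info_r2" %in% names(variants))) variants$info_r2 <- NA_real_
  if (nrow(variants) != ncol(calls)) {
    stop("variant table has ", nrow(variants), " rows but calls has ",
         ncol(calls), " columns")
  }
  if (anyDuplicated(variants$rsid)) {
    stop("duplicate rsid in variant table: ",
         variants$rsid[duplicated(variants$rsid)][1])
  }
  if (any(variants$pos < 1)) stop("positions must be >= 1")
  if (any(variants$ref == variants$alt)) {
    stop("ref and alt allele identical for ",
         variants$rsid[variants$ref == variants$alt][1])
  }
  if (is.null(rownames(calls))) {
    rownames(calls) <- paste0("sample", seq_len(nrow(calls)))
  }
  colnames(calls) <- variants$rsid
  rownames(variants) <- NULL
  structure(list(calls = calls, variants = variants),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants\n",
              nrow(x$calls), ncol(x$calls)))
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  chroms <- unique(x$variants$chrom)
  cat("  chromosomes: ", paste(utils::head(chroms, 10), collapse = ", "),
      if (length(chroms) > 10) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Number of samples / variants in a genotype matrix
#' @param gm A `genotype_matrix`.
#' @return Integer count.
#' @export
n_samples <- function(gm) nrow(gm$calls)

#' @rdname n_samples
#' @export
n_variants <- function(gm) ncol(gm$calls)

#' Subset a genotype matrix
#'
#' @param x A `genotype_matrix`.
#' @param i Sample index (logical, integer or character).
#' @param j Variant index (logical, integer, or rsid character).
#' @param ... Unused.
#' @return A `genotype_matrix` restricted to the selected samples/variants.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$calls))
  if (missing(j)) j <- seq_len(ncol(x$calls))
  if (is.character(j)) j <- match(j, x$variants$rsid)
  if (anyNA(j)) stop("unknown rsid in variant subset")
  genotype_matrix(x$calls[i, j, drop = FALSE],
                  x$variants[j, , drop = FALSE])
}

#' Read a genotype matrix from PLINK .raw or VCF
#'
#' `format = "raw"` expects a PLINK additive-recode file: a whitespace
#' delimited header `FID IID PAT MAT SEX PHENOTYPE <rsid>_<allele> ...`
#' followed by one row per sample whose trailing columns are ALT-allele
#' dosages in `{0, 1, 2, NA}`. Variant metadata (chrom/pos/ref) is not
#' carried by .raw; it can be supplied through `variant_info` or is filled
#' with placeholders. `format = "vcf"` reads hard GT calls through
#' \pkg{vcfR}; records with more than one ALT allele are skipped with a
#' warning, and `INFO/R2` is captured when present.
#'
#' @param path Path to the genotype file.
#' @param format `"raw"` or `"vcf"`.
#' @param variant_info Optional data frame with columns `rsid`, `chrom`,
#'   `pos`, `ref`, `alt` used to attach metadata to .raw input.
#' @return A [genotype_matrix()].
#' @export
load_genotypes <- function(path, format = c("raw", "vcf"),
                           variant_info = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("genotype file not found: ", path)
  if (format == "raw") {
    load_genotypes_raw(path, variant_info)
  } else {
    load_genotypes_vcf(path)
  }
}

load_genotypes_raw <- function(path, variant_info) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1) stop("parse error at line 1: empty .raw file")
  header <- strsplit(trimws(lines[1]), "[ \t]+")[[1]]
  fixed <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (length(header) < 7 || !identical(header[1:6], fixed)) {
    stop("parse error at line 1: expected PLINK .raw header ",
         "'FID IID PAT MAT SEX PHENOTYPE <snp> ...'")
  }
  snp_cols <- header[-(1:6)]
  # <rsid>_<counted allele>; allele suffix optional for robustness
  rsid <- sub("_[^_]*$", "", snp_cols)
  counted <- ifelse(grepl("_[^_]*$", snp_cols),
                    sub("^.*_", "", snp_cols), NA_character_)
  m <- length(snp_cols)
  n <- length(lines) - 1L
  calls <- matrix(NA_integer_, nrow = n, ncol = m)
  ids <- character(n)
  for (k in seq_len(n)) {
    fields <- strsplit(trimws(lines[k + 1L]), "[ \t]+")[[1]]
    if (length(fields) != length(header)) {
      stop("parse error at line ", k + 1L, ": expected ", length(header),
           " fields, found ", length(fields))
    }
    ids[k] <- fields[2]
    dos <- fields[-(1:6)]
    dos[dos %in% c("NA", "na", ".", "-9")] <- NA
    val <- suppressWarnings(as.integer(dos))
    if (any(!is.na(dos) & is.na(val))) {
      stop("parse error at line ", k + 1L, ": non-integer dosage '",
           dos[!is.na(dos) & is.na(val)][1], "'")
    }
    if (any(!is.na(val) & !(val %in% 0:2))) {
      stop("parse error at line ", k + 1L, ": dosage outside {0,1,2}")
    }
    calls[k, ] <- val
  }
  rownames(calls) <- ids
  if (is.null(variant_info)) {
    variants <- data.frame(rsid = rsid, chrom = NA_character_,
                           pos = seq_len(m), ref = "N",
                           alt = ifelse(is.na(counted), "A", counted),
                           info_r2 = NA_real_, stringsAsFactors = FALSE)
    # guard the ref != alt invariant for placeholder metadata
    variants$ref <- ifelse(variants$alt == "N", "A", "N")
  } else {
    idx <- match(rsid, variant_info$rsid)
    if (anyNA(idx)) {
      stop("variant_info lacks metadata for ", rsid[is.na(idx)][1])
    }
    variants <- variant_info[idx, , drop = FALSE]
  }
  genotype_matrix(calls, variants)
}

load_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT) | fix$ALT %in% c(".", "")
  if (any(multi)) {
    warning(sum(multi), " non-biallelic VCF record(s) skipped: ",
            paste(utils::head(fix$ID[multi], 5), collapse = ", "))
  }
  keep <- which(!multi)
  if (!length(keep)) stop("no biallelic records in VCF: ", path)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  info_r2 <- suppressWarnings(as.numeric(
    vcfR::extract.info(vcf, element = "R2")[keep]))
  # count ALT alleles in the GT string, any ploidy separator
  count_alt <- function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_integer_)
    al <- strsplit(g, "[/|]")[[1]]
    if (any(al == ".")) return(NA_integer_)
    sum(al != "0")
  }
  calls <- t(apply(gt, 1, function(row) vapply(row, count_alt, integer(1))))
  if (ncol(gt) == 1) calls <- matrix(calls, ncol = 1)
  calls <- t(calls)  # samples x variants
  if (nrow(gt) == 1) calls <- matrix(calls, ncol = 1)
  rownames(calls) <- colnames(gt)
  rsid <- fix$ID
  rsid[is.na(rsid) | rsid == "."] <- paste0(fix$CHROM, ":", fix$POS)[
    is.na(rsid) | rsid == "."]
  variants <- data.frame(rsid = rsid, chrom = fix$CHROM,
                         pos = as.integer(fix$POS), ref = fix$REF,
                         alt = fix$ALT, info_r2 = info_r2,
                         stringsAsFactors = FALSE)
  genotype_matrix(calls, variants)
}

#' Write a genotype matrix as PLINK .raw
#'
#' @param gm A [genotype_matrix()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_genotypes_raw <- function(gm, path) {
  header <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE",
              paste0(gm$variants$rsid, "_", gm$variants$alt))
  ids <- rownames(gm$calls)
  body <- vapply(seq_len(nrow(gm$calls)), function(i) {
    paste(c(ids[i], ids[i], "0", "0", "0", "-9",
            ifelse(is.na(gm$calls[i, ]), "NA", gm$calls[i, ])),
          collapse = " ")
  }, character(1))
  writeLines(c(paste(header, collapse = " "), body), path)
  invisible(path)
}

#' Compute BMI and its high/low class
#'
#' BMI is weight (kg) divided by squared height (m). The class boundary is
#' inclusive: `bmi >= threshold` is labelled `"high"`, matching the WHO
#' overweight definition at the default threshold of 25 kg/m^2.
#'
#' @param height_cm Height in centimetres, positive.
#' @param weight_kg Weight in kilograms, positive.
#' @param threshold Class boundary in kg/m^2 (default 25).
#' @return A list with numeric `bmi` and character `bmi_class`
#'   (`"high"`/`"low"`), each the common length of the inputs.
#' @examples
#' derive_bmi(175, 70)  # bmi 22.86, class "low"
#' @export
derive_bmi <- function(height_cm, weight_kg, threshold = 25) {
  if (any(!is.finite(height_cm)) || any(!is.finite(weight_kg))) {
    stop("height and weight must be finite")
  }
  if (any(height_cm <= 0) || any(weight_kg <= 0)) {
    stop("height and weight must be positive")
  }
  bmi <- weight_kg / (height_cm / 100)^2
  list(bmi = bmi, bmi_class = ifelse(bmi >= threshold, "high", "low"))
}

#' Read a phenotype/covariate table
#'
#' Expects a TSV with a header naming a sample-id column (`sample_id`, `IID`
#' or `id`) plus either `height_cm`/`height` and `weight_kg`/`weight`, or a
#' `bmi` column directly, and `age` and `sex` covariates. Rows missing any
#' required field are dropped and counted in the `n_dropped` attribute.
#'
#' @param path Path to the TSV file.
#' @param bmi_threshold Class boundary passed to [derive_bmi()].
#' @return A data frame of class `phenotype_table` with columns `sample_id`,
#'   `bmi`, `bmi_class`, `age`, `sex` (and `height_cm`, `weight_kg` when
#'   present), plus attribute `n_dropped`.
#' @export
load_phenotypes <- function(path, bmi_threshold = 25) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0) stop("no phenotype rows in ", path)
  pick <- function(cands) {
    hit <- intersect(cands, names(df))
    if (length(hit)) hit[1] else NA_character_
  }
  id_col <- pick(c("sample_id", "IID", "iid", "id"))
  if (is.na(id_col)) stop("phenotype file lacks a sample id column")
  age_col <- pick(c("age", "AGE"))
  sex_col <- pick(c("sex", "SEX", "gender"))
  if (is.na(age_col) || is.na(sex_col)) {
    stop("phenotype file must contain age and sex columns")
  }
  bmi_col <- pick(c("bmi", "BMI"))
  h_col <- pick(c("height_cm", "height"))
  w_col <- pick(c("weight_kg", "weight"))
  if (is.na(bmi_col) && (is.na(h_col) || is.na(w_col))) {
    stop("phenotype file needs either bmi or both height and weight")
  }
  out <- data.frame(sample_id = as.character(df[[id_col]]),
                    age = as.numeric(df[[age_col]]),
                    sex = as.integer(df[[sex_col]]),
                    stringsAsFactors = FALSE)
  if (!is.na(h_col)) out$height_cm <- as.numeric(df[[h_col]])
  if (!is.na(w_col)) out$weight_kg <- as.numeric(df[[w_col]])
  if (!is.na(bmi_col)) {
    out$bmi <- as.numeric(df[[bmi_col]])
  } else {
    out$bmi <- NA_real_
    ok <- !is.na(out$height_cm) & !is.na(out$weight_kg) &
      out$height_cm > 0 & out$weight_kg > 0
    if (any(ok)) {
      out$bmi[ok] <- derive_bmi(out$height_cm[ok], out$weight_kg[ok],
                                bmi_threshold)$bmi
    }
  }
  complete <- !is.na(out$bmi) & out$bmi > 0 & !is.na(out$age) &
    !is.na(out$sex) & out$sex %in% c(0L, 1L)
  n_dropped <- sum(!complete)
  out <- out[complete, , drop = FALSE]
  if (nrow(out) == 0) stop("no phenotype rows survive completeness filter")
  out$bmi_class <- ifelse(out$bmi >= bmi_threshold, "high", "low")
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("phenotype_table", "data.frame")
  out
}

#' Write a phenotype table as TSV
#'
#' @param pheno A `phenotype_table` (or compatible data frame).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.table(as.data.frame(pheno), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align a genotype matrix and phenotype table on shared samples
#'
#' @param gm A [genotype_matrix()].
#' @param pheno A phenotype table with a `sample_id` column.
#' @return A list with the subset `gm` and `pheno` in matching sample order.
#' @export
align_samples <- function(gm, pheno) {
  shared <- intersect(rownames(gm$calls), pheno$sample_id)
  if (!length(shared)) {
    stop("no overlap between genotype and phenotype sample ids")
  }
  gm2 <- gm[match(shared, rownames(gm$calls)), ]
  ph2 <- pheno[match(shared, pheno$sample_id), , drop = FALSE]
  rownames(ph2) <- NULL
  list(gm = gm2, pheno = ph2)
}

pair_result_columns <- c("snp1", "snp2", "method", "statistic",
                         "p_nominal", "p_adjusted")

#' Write / read pair-result tables
#'
#' Results are stored as TSV with one row per (pair, method) and 15
#' significant digits, so a write/read round trip is lossless to well past
#' 12 significant digits.
#'
#' @param results Data frame with columns `snp1`, `snp2`, `method`,
#'   `statistic`, `p_nominal`, `p_adjusted` (extra columns are preserved).
#' @param path File path.
#' @return `write_results` invisibly returns `path`; `read_results` returns
#'   the data frame.
#' @export
write_results <- function(results, path) {
  results <- as.data.frame(results)
  missing_cols <- setdiff(pair_result_columns, names(results))
  for (cc in missing_cols) results[[cc]] <- NA
  results <- results[, c(pair_result_columns,
                         setdiff(names(results), pair_result_columns)),
                     drop = FALSE]
  fmt <- results
  num <- vapply(fmt, is.numeric, logical(1))
  fmt[num] <- lapply(fmt[num], function(x) {
    ifelse(is.na(x), "NA", sprintf("%.15g", x))
  })
  utils::write.table(fmt, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("results file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = NA, na.strings = "NA")
  for (cc in c("statistic", "p_nominal", "p_adjusted")) {
    if (cc %in% names(df)) df[[cc]] <- as.numeric(df[[cc]])
  }
  df
}
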