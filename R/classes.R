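#' @importFrom stats lm pf pt qnorm rbinom rnorm runif sd var anova
#' @importFrom utils head read.delim write.table combn
NULL

#' Construct a genotype matrix
#'
#' Container for sample-by-variant allele dosages together with the variant
#' metadata needed for allele harmonization and QC. Dosages are expected
#' counts of allele `a1` in `[0, 2]`; `NA` marks missing genotypes.
#'
#' @param dosages numeric matrix, samples in rows, variants in columns.
#'   Row names are sample ids, column names variant ids.
#' @param variants data.frame with columns `variant_id`, `chrom`, `pos`,
#'   `a1` (counted allele), `a2` (other allele) and optionally `info_r2`
#'   (imputation quality in `[0, 1]`, `NA` when unavailable).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, variants) {
  stopifnot(is.matrix(dosages), is.data.frame(variants))
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  req <- c("variant_id", "chrom", "pos", "a1", "a2")
  if (!all(req %in% names(variants)))
    stop("variants must have columns: ", paste(req, collapse = ", "))
  if (!"info_r2" %in% names(variants)) variants$info_r2 <- NA_real_
  if (ncol(dosages) != nrow(variants))
    stop("dosages has ", ncol(dosages), " columns but variants has ",
         nrow(variants), " rows")
  if (anyDuplicated(variants$variant_id))
    stop("duplicate variant id: ",
         variants$variant_id[duplicated(variants$variant_id)][1])
  if (is.null(rownames(dosages)))
    stop("dosages must carry sample ids as row names")
  if (anyDuplicated(rownames(dosages)))
    stop("duplicate sample id: ",
         rownames(dosages)[duplicated(rownames(dosages))][1])
  if (any(variants$pos < 1)) stop("variant positions must be >= 1")
  bad <- variants$a1 == variants$a2
  if (any(bad)) stop("allele a1 == a2 for variant ",
                     variants$variant_id[bad][1])
  rng <- range(dosages, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2))
    stop("dosages must lie in [0, 2]")
  colnames(dosages) <- variants$variant_id
  structure(list(dosages = dosages, variants = variants),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosages), "samples x",
      ncol(x$dosages), "variants;",
      sum(is.na(x$dosages)), "missing dosages\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Sample ids of a genotype matrix
#' @param g a `genotype_matrix`.
#' @return character vector of sample ids in storage order.
#' @export
gm_samples <- function(g) rownames(g$dosages)

#' Construct a weight set
#'
#' A named set of per-variant effect weights defining one polygenic score.
#' The non-zero-weight subset (weight exactly != 0) drives pathway
#' partitioning.
#'
#' @param prs_name score name.
#' @param entries data.frame with columns `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `weight`.
#' @return An object of class `weight_set`.
#' @export
weight_set <- function(prs_name, entries) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  req <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
           "weight")
  if (!all(req %in% names(entries)))
    stop("entries must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(entries$variant_id))
    stop("duplicate variant id in weight set: ",
         entries$variant_id[duplicated(entries$variant_id)][1])
  if (any(!is.finite(entries$weight)))
    stop("non-finite weight for variant ",
         entries$variant_id[!is.finite(entries$weight)][1])
  structure(list(prs_name = prs_name, entries = entries[req]),
            class = "weight_set")
}

#' @export
print.weight_set <- function(x, ...) {
  cat("weight_set '", x$prs_name, "': ", nrow(x$entries), " variants (",
      sum(x$entries$weight != 0), " non-zero)\n", sep = "")
  invisible(x)
}

#' QC thresholds for variant filtering
#'
#' Defaults reproduce the filters commonly applied to imputed array data:
#' MAF > 0.01, missing rate < 0.05, Hardy-Weinberg exact p > 5e-7 and
#' imputation r2 > 0.3.
#'
#' @param min_maf retain variants with folded minor allele frequency
#'   strictly greater than this.
#' @param max_missing retain variants with missing rate strictly below this.
#' @param min_hwe_p retain variants with HWE exact p strictly greater.
#' @param min_info_r2 retain variants with imputation quality strictly
#'   greater; variants lacking an info score are not tested on this rule.
#' @return list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_maf = 0.01, max_missing = 0.05,
                          min_hwe_p = 5e-7, min_info_r2 = 0.3) {
  v <- c(min_maf, max_missing, min_hwe_p, min_info_r2)
  if (any(v < 0 | v > 1)) stop("all QC thresholds must lie in [0, 1]")
  structure(list(min_maf = min_maf, max_missing = max_missing,
                 min_hwe_p = min_hwe_p, min_info_r2 = min_info_r2),
            class = "qc_thresholds")
}

#' Construct a phenotype table
#'
#' Longitudinal phenotype container: static covariates (sex, 10 genetic
#' PCs) per sample and a long-format measurement table with one row per
#' sample, phenotype and measurement wave.
#'
#' @param covariates data.frame with `sample_id`, `sex` (0/1; reference
#'   level 0 = female by convention) and `PC1`..`PC10`.
#' @param measurements data.frame with `sample_id`, `phenotype`, `wave`,
#'   `age` (years at measurement) and `value`.
#' @param phenotype_info data.frame with `phenotype`, `category` and
#'   logical `is_age_of_initiation` (when TRUE the age covariate is
#'   dropped from association models for that phenotype).
#' @return object of class `phenotype_table`.
#' @export
phenotype_table <- function(covariates, measurements, phenotype_info = NULL) {
  covariates <- as.data.frame(covariates, stringsAsFactors = FALSE)
  measurements <- as.data.frame(measurements, stringsAsFactors = FALSE)
  if (anyDuplicated(covariates$sample_id))
    stop("duplicate sample_id in covariates")
  if (!all(c("sample_id", "sex") %in% names(covariates)))
    stop("covariates need sample_id and sex")
  pcs <- paste0("PC", 1:10)
  if (!all(pcs %in% names(covariates)))
    stop("covariates need columns PC1..PC10")
  req <- c("sample_id", "phenotype", "wave", "age", "value")
  if (!all(req %in% names(measurements)))
    stop("measurements need columns: ", paste(req, collapse = ", "))
  if (any(measurements$age <= 0, na.rm = TRUE))
    stop("ages must be positive")
  key <- paste(measurements$sample_id, measurements$phenotype,
               measurements$wave)
  if (anyDuplicated(key))
    stop("more than one measurement per sample/phenotype/wave")
  if (is.null(phenotype_info)) {
    phenotype_info <- data.frame(
      phenotype = unique(measurements$phenotype),
      category = "unlabelled",
      is_age_of_initiation = FALSE,
      stringsAsFactors = FALSE)
  }
  structure(list(covariates = covariates, measurements = measurements,
                 phenotype_info = as.data.frame(phenotype_info)),
            class = "phenotype_table")
}

#' @export
print.phenotype_table <- function(x, ...) {
  cat("phenotype_table:", nrow(x$covariates), "samples,",
      length(unique(x$measurements$phenotype)), "phenotypes,",
      nrow(x$measurements), "measurements\n")
  invisible(x)
}
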