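# Raw and standardized polygenic score computation.

#' Compute a polygenic score
#'
#' Raw score for sample s is `sum_j weight_j * dosage_sj` over the
#' variants shared between the weight set and the genotype matrix.
#' Missing dosages are handled per `missing_policy`: `"mean_impute"`
#' (default) substitutes the variant's mean dosage over non-missing
#' samples, `"omit"` skips the term for that sample.
#'
#' @param g a [genotype_matrix()].
#' @param w a [weight_set()] already harmonized to `g` (effect allele ==
#'   `g`'s counted allele `a1`); see [harmonize_weights()].
#' @param missing_policy `"mean_impute"` or `"omit"`.
#' @return a `score_vector`: data.frame with `sample_id`, `raw`,
#'   `standardized` (NA until [standardize()] is called), attributes
#'   `prs_name` and `n_snps_used`.
#' @export
compute_prs <- function(g, w, missing_policy = c("mean_impute", "omit")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(g, "genotype_matrix"), inherits(w, "weight_set"))
  idx <- match(w$entries$variant_id, g$variants$variant_id)
  use <- !is.na(idx)
  if (!any(use))
    stop("no overlapping variants between genotypes and weight set '",
         w$prs_name, "'")
  wv <- w$entries$weight[use]
  d <- g$dosages[, idx[use], drop = FALSE]
  if (missing_policy == "mean_impute") {
    allmiss <- colSums(!is.na(d)) == 0
    if (any(allmiss))
      stop("variant with all dosages missing under mean_impute: ",
           colnames(d)[allmiss][1])
    if (anyNA(d)) {
      mu <- colMeans(d, na.rm = TRUE)
      na_idx <- which(is.na(d), arr.ind = TRUE)
      d[na_idx] <- mu[na_idx[, 2]]
    }
    raw <- as.numeric(d %*% wv)
  } else {
    d0 <- d; d0[is.na(d0)] <- 0
    raw <- as.numeric(d0 %*% wv)
  }
  out <- data.frame(sample_id = rownames(g$dosages), raw = raw,
                    standardized = NA_real_, stringsAsFactors = FALSE)
  attr(out, "prs_name") <- w$prs_name
  attr(out, "n_snps_used") <- sum(use)
  class(out) <- c("score_vector", "data.frame")
  out
}

#' Standardize a score vector to zero mean and unit variance
#'
#' Uses the sample standard deviation (n-1 denominator) over the full
#' scored sample.
#'
#' @param sv a `score_vector` from [compute_prs()].
#' @return the score vector with its `standardized` column filled.
#' @export
standardize <- function(sv) {
  stopifnot(inherits(sv, "score_vector"))
  mu <- mean(sv$raw)
  s <- stats::sd(sv$raw)
  if (!is.finite(s) || s == 0)
    stop("degenerate score: raw values of '", attr(sv, "prs_name"),
         "' have zero variance")
  sv$standardized <- (sv$raw - mu) / s
  sv
}

#' Restrict a weight set to a variant subset
#'
#' Used by pathway partitioning to build pathway-specific scores.
#'
#' @param w a [weight_set()].
#' @param variant_subset character vector of variant ids to keep.
#' @return a [weight_set()] containing only the intersecting entries.
#' @export
restrict_weights <- function(w, variant_subset) {
  stopifnot(inherits(w, "weight_set"))
  keep <- w$entries$variant_id %in% variant_subset
  if (!any(keep))
    stop("empty intersection: no weight-set variant in the subset")
  weight_set(w$prs_name, w$entries[keep, , drop = FALSE])
}

#' @export
print.score_vector <- function(x, ...) {
  cat("score_vector '", attr(x, "prs_name"), "': ", nrow(x),
      " samples, ", attr(x, "n_snps_used"), " SNPs used\n", sep = "")
  invisible(as.data.frame(x))
}

#' Write scores to TSV
#' @param scores list of `score_vector`s (or a single one).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  if (inherits(scores, "score_vector")) scores <- list(scores)
  tab <- do.call(rbind, lapply(scores, function(sv)
    data.frame(sample_id = sv$sample_id,
               prs_name = attr(sv, "prs_name"),
               raw = sv$raw, standardized = sv$standardized,
               stringsAsFactors = FALSE)))
  data.table::fwrite(tab, path, sep = "\t", quote = FALSE)
  invisible(path)
}
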