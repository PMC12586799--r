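# PRS-by-sex moderation: naive interaction model and the robust model
# that saturates the design with covariate products.

#' Test PRS x sex interaction
#'
#' Naive model: `y ~ s + sex + cov + s:sex`. Robust model additionally
#' includes `cov_j : s` and `cov_j : sex` for every non-sex covariate
#' `j` (age and each PC), which guards the interaction estimate against
#' bias from unmodelled covariate products. Sex must be coded 0/1
#' (reference level 0); `beta_int` is then the male-minus-female
#' difference in the per-SD score effect when 1 codes male.
#'
#' `delta_adj_r2_int_pct` is the adjusted-R2 gain of the `s:sex` term
#' over the same model without it, on the percent scale.
#'
#' @param y phenotype vector.
#' @param s standardized score.
#' @param sex 0/1 vector with both levels present.
#' @param cov covariate matrix (age, PCs); NULL for none.
#' @param model `"robust"` (default) or `"naive"`.
#' @return one-row data.frame: `model`, `n`, `beta_main`, `se_main`,
#'   `p_main`, `beta_int`, `se_int`, `p_int`, `delta_adj_r2_int_pct`.
#' @export
fit_interaction <- function(y, s, sex, cov = NULL,
                            model = c("robust", "naive")) {
  model <- match.arg(model)
  if (!all(sex %in% c(0, 1, NA)))
    stop("sex must be coded 0/1")
  if (!is.null(cov)) {
    cov <- as.matrix(cov)
    if (is.null(colnames(cov)))
      colnames(cov) <- paste0("c", seq_len(ncol(cov)))
  }
  ok <- !is.na(y) & !is.na(s) & !is.na(sex)
  if (!is.null(cov)) ok <- ok & !rowSums(is.na(cov))
  y <- y[ok]; s <- s[ok]; sex <- sex[ok]
  if (!is.null(cov)) cov <- cov[ok, , drop = FALSE]
  if (length(unique(sex)) < 2)
    stop("single-sex sample: interaction not estimable")
  X <- cbind(`(Intercept)` = 1, score = s, sex = sex, cov,
             `score:sex` = s * sex)
  if (model == "robust" && !is.null(cov)) {
    prod_s <- cov * s
    colnames(prod_s) <- paste0(colnames(cov), ":score")
    prod_sex <- cov * sex
    colnames(prod_sex) <- paste0(colnames(cov), ":sex")
    X <- cbind(X, prod_s, prod_sex)
  }
  n <- length(y)
  if (n < ncol(X) + 2)
    stop("too few complete cases (", n, ") for the ", model,
         " design with ", ncol(X), " columns")
  full <- ols_fit(X, y)
  red <- ols_fit(X[, colnames(X) != "score:sex", drop = FALSE], y)
  d_adj <- adj_r2(full$r2, n, ncol(X) - 1L) -
    adj_r2(red$r2, n, ncol(X) - 2L)
  data.frame(model = model, n = n,
             beta_main = unname(full$coef["score"]),
             se_main = unname(full$se["score"]),
             p_main = unname(full$p["score"]),
             beta_int = unname(full$coef["score:sex"]),
             se_int = unname(full$se["score:sex"]),
             p_int = unname(full$p["score:sex"]),
             delta_adj_r2_int_pct = 100 * d_adj,
             stringsAsFactors = FALSE)
}

#' Run interaction models across the phenome
#'
#' Fits [fit_interaction()] for every PRS x phenotype x wave pair, with
#' BH q-values for the score main effect and the interaction term
#' computed separately within each PRS family (mirroring the
#' association-scan families).
#'
#' @param scores list of standardized `score_vector`s.
#' @param pt a [phenotype_table()].
#' @param model `"robust"` or `"naive"`.
#' @param covariate_pcs number of PCs in the covariate set.
#' @return data.frame with per-pair interaction inference plus `q_main`
#'   and `q_int`.
#' @export
run_interactions <- function(scores, pt, model = c("robust", "naive"),
                             covariate_pcs = 10) {
  model <- match.arg(model)
  if (inherits(scores, "score_vector")) scores <- list(scores)
  pw <- unique(pt$measurements[, c("phenotype", "wave")])
  rows <- list()
  for (sv in scores) {
    for (i in seq_len(nrow(pw))) {
      ph <- pw$phenotype[i]; wv <- pw$wave[i]
      a <- assemble_pair(sv, pt, ph, wv, covariate_pcs)
      sex <- a$cov[, "sex"]
      cov <- a$cov[, colnames(a$cov) != "sex", drop = FALSE]
      fit <- fit_interaction(a$y, a$s, sex, cov, model)
      rows[[length(rows) + 1L]] <- data.frame(
        prs = attr(sv, "prs_name"), phenotype = ph, wave = wv, fit,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  res$q_main <- NA_real_; res$q_int <- NA_real_
  for (prs in unique(res$prs)) {
    sel <- res$prs == prs
    res$q_main[sel] <- bh_adjust(res$p_main[sel])
    res$q_int[sel] <- bh_adjust(res$p_int[sel])
  }
  res
}

#' Flag significant PRS x sex interactions
#'
#' Conjunction rule: a pair is flagged only when both the score main
#' effect and the interaction term pass the FDR threshold in the robust
#' model (`q_main < alpha` AND `q_int < alpha`).
#'
#' @param results output of [run_interactions()].
#' @param alpha FDR threshold (default 0.05).
#' @return the subset of flagged rows (possibly empty).
#' @export
flag_significant_interactions <- function(results, alpha = 0.05) {
  if (nrow(results) == 0) return(results)
  results[results$q_main < alpha & results$q_int < alpha, , drop = FALSE]
}
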