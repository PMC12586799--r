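# Phenome-wide association scan: per-pair linear models, delta adjusted
# R-squared effect sizes, BH q-values within per-PRS families.

# least-squares fit with coefficient inference; X must include intercept
ols_fit <- function(X, y) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    piv <- qx$pivot
    dropped <- colnames(X)[piv[(qx$rank + 1):ncol(X)]]
    stop("singular fit: collinear column(s) ",
         paste(dropped, collapse = ", "))
  }
  n <- length(y)
  coefs <- qr.coef(qx, y)
  res <- y - X %*% coefs
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  df_res <- n - ncol(X)
  sigma2 <- rss / df_res
  XtXinv <- chol2inv(qr.R(qx))[order(qx$pivot), order(qx$pivot), drop = FALSE]
  se <- sqrt(diag(XtXinv) * sigma2)
  names(se) <- colnames(X)
  tval <- coefs / se
  pval <- 2 * stats::pt(abs(tval), df_res, lower.tail = FALSE)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  list(coef = coefs, se = se, p = pval, r2 = r2, rss = rss, n = n,
       k = ncol(X) - 1L, df_res = df_res)
}

adj_r2 <- function(r2, n, k) 1 - (1 - r2) * (n - 1) / (n - k - 1)

#' Linear association of one phenotype with one standardized score
#'
#' Ordinary least squares of `y` on `[intercept, s, cov]`. Inference
#' (two-sided t) is reported for `s`. The effect measure is the
#' difference in adjusted R-squared between the full model and the
#' covariate-only model, `adjR2 = 1 - (1 - R2)(n - 1)/(n - k - 1)` with
#' `k` the number of non-intercept predictors, reported on the percent
#' scale. It may be negative.
#'
#' Rows with any missing value among `y`, `s` and `cov` are dropped
#' (complete-case analysis).
#'
#' @param y numeric phenotype vector.
#' @param s standardized score vector, same length as `y`.
#' @param cov covariate matrix (or NULL for none); columns should be
#'   named.
#' @return one-row data.frame: `n`, `beta`, `se`, `p`,
#'   `delta_adj_r2_pct`.
#' @export
fit_linear_assoc <- function(y, s, cov = NULL) {
  if (!is.null(cov)) {
    cov <- as.matrix(cov)
    if (is.null(colnames(cov))) colnames(cov) <- paste0("c", seq_len(ncol(cov)))
  }
  ok <- !is.na(y) & !is.na(s)
  if (!is.null(cov)) ok <- ok & !rowSums(is.na(cov))
  y <- y[ok]; s <- s[ok]
  if (!is.null(cov)) cov <- cov[ok, , drop = FALSE]
  k_full <- 1L + if (is.null(cov)) 0L else ncol(cov)
  n <- length(y)
  if (n < k_full + 3L)
    stop("too few complete cases (", n, ") for ", k_full + 1L, " parameters")
  if (stats::var(y) == 0) stop("phenotype has zero variance")
  X_full <- cbind(`(Intercept)` = 1, score = s, cov)
  full <- ols_fit(X_full, y)
  if (is.null(cov)) {
    r2_red <- 0; k_red <- 0L
  } else {
    red <- ols_fit(cbind(`(Intercept)` = 1, cov), y)
    r2_red <- red$r2; k_red <- ncol(cov)
  }
  d_adj <- adj_r2(full$r2, n, k_full) - adj_r2(r2_red, n, k_red)
  data.frame(n = n, beta = unname(full$coef["score"]),
             se = unname(full$se["score"]), p = unname(full$p["score"]),
             delta_adj_r2_pct = 100 * d_adj)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up procedure: with `p_(1) <= ... <= p_(m)`,
#' `q_(i) = min_{j >= i} min(1, p_(j) * m / j)`, mapped back to the
#' input order. Ties share a value. NA p-values propagate as NA and do
#' not count toward the family size.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return vector of BH q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  pv <- p[ok]
  m <- length(pv)
  if (m == 0) return(q)
  o <- order(pv)
  adj <- pmin(1, pv[o] * m / seq_len(m))
  adj <- rev(cummin(rev(adj)))
  qv <- numeric(m); qv[o] <- adj
  q[ok] <- qv
  q
}

# assemble the analysis frame for one phenotype/wave: y, score, covariates
assemble_pair <- function(sv, pt, pheno, wave_id, covariate_pcs = 10) {
  mm <- pt$measurements
  rows <- mm$phenotype == pheno & mm$wave == wave_id
  mrows <- mm[rows, , drop = FALSE]
  ci <- match(mrows$sample_id, pt$covariates$sample_id)
  si <- match(mrows$sample_id, sv$sample_id)
  keep <- !is.na(ci) & !is.na(si)
  mrows <- mrows[keep, , drop = FALSE]
  info <- pt$phenotype_info
  aoi <- isTRUE(info$is_age_of_initiation[match(pheno, info$phenotype)])
  pcs <- paste0("PC", seq_len(covariate_pcs))
  cov <- as.matrix(pt$covariates[ci[keep], c("sex", pcs), drop = FALSE])
  if (!aoi) cov <- cbind(age = mrows$age, cov)
  list(y = mrows$value, s = sv$standardized[si[keep]], cov = cov,
       mean_age = mean(mrows$age, na.rm = TRUE), aoi = aoi)
}

#' Phenome-wide association scan
#'
#' Fits every PRS x phenotype x wave pair by linear regression of the
#' phenotype on the standardized score, adjusting for sex, age at
#' measurement (omitted for phenotypes flagged `is_age_of_initiation`)
#' and the first 10 PCs. Benjamini-Hochberg adjustment is applied
#' separately within each PRS across all of its phenotype/wave tests;
#' rows with `q < alpha` are flagged significant.
#'
#' @param scores list of standardized `score_vector`s.
#' @param pt a [phenotype_table()].
#' @param alpha significance level on the q scale (default 0.05).
#' @param covariate_pcs how many PCs to adjust for (default 10).
#' @return data.frame of class `assoc_table`: `prs`, `phenotype`,
#'   `category`, `wave`, `mean_age`, `n`, `beta`, `se`, `p`, `q`,
#'   `delta_adj_r2_pct`, `significant`.
#' @export
run_phewas <- function(scores, pt, alpha = 0.05, covariate_pcs = 10) {
  if (inherits(scores, "score_vector")) scores <- list(scores)
  stopifnot(length(scores) >= 1, inherits(pt, "phenotype_table"))
  pw <- unique(pt$measurements[, c("phenotype", "wave")])
  info <- pt$phenotype_info
  rows <- list()
  for (sv in scores) {
    if (all(is.na(sv$standardized)))
      stop("score '", attr(sv, "prs_name"), "' is not standardized")
    for (i in seq_len(nrow(pw))) {
      ph <- pw$phenotype[i]; wv <- pw$wave[i]
      a <- assemble_pair(sv, pt, ph, wv, covariate_pcs)
      if (all(is.na(a$y))) {
        warning("phenotype ", ph, " wave ", wv,
                " has no non-missing values; skipped")
        next
      }
      fit <- fit_linear_assoc(a$y, a$s, a$cov)
      rows[[length(rows) + 1L]] <- data.frame(
        prs = attr(sv, "prs_name"), phenotype = ph,
        category = info$category[match(ph, info$phenotype)],
        wave = wv, mean_age = a$mean_age, fit,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  res$q <- NA_real_
  for (prs in unique(res$prs)) {
    sel <- res$prs == prs
    res$q[sel] <- bh_adjust(res$p[sel])
  }
  res$significant <- res$q < alpha
  class(res) <- c("assoc_table", "data.frame")
  res
}

#' Validate PRSs against their target or proxy phenotypes
#'
#' One association per PRS (its designated validation phenotype at the
#' designated wave), BH-adjusted across the PRS set; a PRS is retained
#' for the phenome-wide scan iff `q < alpha`.
#'
#' @param scores list of standardized `score_vector`s.
#' @param pt a [phenotype_table()].
#' @param validation_map data.frame with `prs`, `phenotype` and
#'   optionally `wave` (defaults to the first wave of that phenotype).
#' @param alpha retention threshold on the q scale (default 0.05).
#' @return data.frame: `prs`, `phenotype`, `wave`, `n`, `beta`, `se`,
#'   `p`, `q`, `adj_r2_pct`, `retained`.
#' @export
validate_prs <- function(scores, pt, validation_map, alpha = 0.05) {
  if (inherits(scores, "score_vector")) scores <- list(scores)
  names(scores) <- vapply(scores, attr, character(1), "prs_name")
  rows <- lapply(seq_len(nrow(validation_map)), function(i) {
    prs <- validation_map$prs[i]
    ph <- validation_map$phenotype[i]
    sv <- scores[[prs]]
    if (is.null(sv)) stop("no score named '", prs, "'")
    waves <- unique(pt$measurements$wave[pt$measurements$phenotype == ph])
    if (length(waves) == 0)
      stop("validation phenotype '", ph, "' absent for PRS '", prs, "'")
    wv <- if ("wave" %in% names(validation_map) &&
              !is.na(validation_map$wave[i])) validation_map$wave[i]
          else waves[1]
    a <- assemble_pair(sv, pt, ph, wv)
    fit <- fit_linear_assoc(a$y, a$s, a$cov)
    data.frame(prs = prs, phenotype = ph, wave = wv, fit,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  names(res)[names(res) == "delta_adj_r2_pct"] <- "adj_r2_pct"
  res$q <- bh_adjust(res$p)
  res$retained <- res$q < alpha
  res
}

#' Compare two association runs (sensitivity analysis)
#'
#' Regresses run `b`'s effect sizes on run `a`'s over their shared
#' (prs, phenotype, wave) keys — the before/after comparison used when a
#' subset of participants is excluded and the scan repeated. Also
#' reports the fraction of `b`'s 95% CIs that cover `a`'s point
#' estimates.
#'
#' @param a,b `assoc_table`s from [run_phewas()].
#' @return list: `slope`, `intercept`, `r2`, `ci_overlap`, `n_shared`.
#' @export
compare_runs <- function(a, b) {
  key <- function(x) paste(x$prs, x$phenotype, x$wave, sep = "\r")
  ka <- key(a); kb <- key(b)
  shared <- intersect(ka, kb)
  if (length(shared) < 3)
    stop("need at least 3 shared (prs, phenotype, wave) keys; got ",
         length(shared))
  ia <- match(shared, ka); ib <- match(shared, kb)
  xa <- a$beta[ia]; xb <- b$beta[ib]
  fit <- stats::lm(xb ~ xa)
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits warn
  ci_lo <- xb - 1.959964 * b$se[ib]
  ci_hi <- xb + 1.959964 * b$se[ib]
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = r2,
       ci_overlap = mean(xa >= ci_lo & xa <= ci_hi),
       n_shared = length(shared))
}

#' Write an association table to TSV
#' @param res `assoc_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_assoc <- function(res, path) {
  data.table::fwrite(as.data.frame(res), path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Pairwise correlation matrix of standardized scores (convenience)
#' @param scores list of standardized `score_vector`s.
#' @return correlation matrix.
#' @export
score_correlation <- function(scores) {
  m <- sapply(scores, function(sv) sv$standardized)
  colnames(m) <- vapply(scores, attr, character(1), "prs_name")
  stats::cor(m, use = "pairwise.complete.obs")
}
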