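# Developmental trends: association strength (delta adjusted R2) as a
# smooth function of mean participant age across measurement waves.

safe_F <- function(rss_red, rss_full, df_num, df_den, scale) {
  if (df_den <= 0) return(list(F = NA_real_, p = NA_real_))
  tiny <- 1e-12 * max(scale, 1)
  num <- (rss_red - rss_full) / df_num
  den <- rss_full / df_den
  if (den <= tiny) {
    if (num <= tiny) return(list(F = 0, p = 1))
    return(list(F = Inf, p = 0))
  }
  Fv <- max(0, num / den)
  list(F = Fv, p = stats::pf(Fv, df_num, df_den, lower.tail = FALSE))
}

trend_df_rule <- function(n_points) {
  if (n_points > 3) 3L else if (n_points == 3) 2L else 1L
}

#' Fit an age trend to per-wave association strengths
#'
#' Given points `(mean_age, delta_adj_r2)` — one per measurement wave —
#' fits three nested models: intercept-only, linear in age, and a
#' natural cubic regression spline with `df_used` degrees of freedom
#' (knots at age quantiles). `df_used` is 3 when there are more than 3
#' points and 2 with exactly 3 points. `p_linear` is the F-ratio test of
#' the linear model against the intercept (the parametric component);
#' `p_nonlinear` the F-ratio of the spline against the linear model (the
#' non-parametric component). With fewer residual degrees of freedom
#' than the test needs, the corresponding p is `NA`.
#'
#' @param points data.frame with columns `mean_age` and `delta_adj_r2`
#'   (percent), optionally `n` and `wave`.
#' @param weight_by_n weight points by their per-wave sample size
#'   (default FALSE: equal weights).
#' @param grid_length prediction grid resolution (default 100).
#' @return object of class `trend_result`: `points`, `df_used`,
#'   `F_linear`, `p_linear`, `F_nonlinear`, `p_nonlinear`, `slope`
#'   (linear-model slope, percent per year) and `grid` (data.frame
#'   `age`, `fit`, `lo95`, `hi95`; bands NA until bootstrapped).
#' @export
fit_trend <- function(points, weight_by_n = FALSE, grid_length = 100) {
  points <- as.data.frame(points)
  stopifnot(all(c("mean_age", "delta_adj_r2") %in% names(points)))
  points <- points[order(points$mean_age), , drop = FALSE]
  np <- nrow(points)
  if (np < 2) stop("at least 2 points required for a trend")
  if (any(diff(points$mean_age) <= 0))
    stop("mean ages must be distinct across waves")
  wts <- if (weight_by_n && "n" %in% names(points)) points$n / mean(points$n)
         else rep(1, np)
  age <- points$mean_age
  y <- points$delta_adj_r2
  tss <- sum(wts * (y - stats::weighted.mean(y, wts))^2)

  wrss <- function(fit) sum(wts * stats::residuals(fit)^2)
  m0 <- stats::lm(y ~ 1, weights = wts)
  m1 <- stats::lm(y ~ age, weights = wts)
  lin <- safe_F(wrss(m0), wrss(m1), 1, np - 2, tss)

  grid_age <- seq(min(age), max(age), length.out = grid_length)
  if (np >= 3) {
    df_used <- trend_df_rule(np)
    basis <- splines::ns(age, df = df_used)
    m2 <- stats::lm(y ~ basis, weights = wts)
    nl <- safe_F(wrss(m1), wrss(m2), df_used - 1, np - 1 - df_used, tss)
    pred <- as.numeric(cbind(1, stats::predict(basis, grid_age)) %*%
                         stats::coef(m2))
  } else {
    df_used <- 1L
    nl <- list(F = NA_real_, p = NA_real_)
    pred <- stats::coef(m1)[1] + stats::coef(m1)[2] * grid_age
  }
  structure(list(
    points = points, df_used = df_used,
    slope = unname(stats::coef(m1)[2]),
    F_linear = lin$F, p_linear = lin$p,
    F_nonlinear = nl$F, p_nonlinear = nl$p,
    grid = data.frame(age = grid_age, fit = pred,
                      lo95 = NA_real_, hi95 = NA_real_)),
    class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat("trend_result:", nrow(x$points), "waves, spline df", x$df_used,
      "\n  p_linear =", format(x$p_linear, digits = 3),
      " p_nonlinear =", format(x$p_nonlinear, digits = 3), "\n")
  invisible(x)
}

# per-wave delta adjusted R2 for one phenotype given sample indices
wave_r2_points <- function(std_score, sample_ids, pt, phenotype,
                           covariate_pcs = 10) {
  sv <- data.frame(sample_id = sample_ids, raw = NA_real_,
                   standardized = std_score, stringsAsFactors = FALSE)
  attr(sv, "prs_name") <- "boot"
  class(sv) <- c("score_vector", "data.frame")
  waves <- unique(pt$measurements$wave[pt$measurements$phenotype ==
                                         phenotype])
  do.call(rbind, lapply(waves, function(wv) {
    a <- assemble_pair(sv, pt, phenotype, wv, covariate_pcs)
    fit <- fit_linear_assoc(a$y, a$s, a$cov)
    data.frame(wave = wv, mean_age = a$mean_age,
               delta_adj_r2 = fit$delta_adj_r2_pct, n = fit$n)
  }))
}

#' Bootstrap confidence bands for an age trend
#'
#' Resamples individuals with replacement, recomputes the per-wave
#' delta adjusted R2 for the given phenotype, refits the trend, and
#' takes the pointwise 2.5/97.5 percentile envelope on the age grid.
#' A degenerate resample (zero score variance) is redrawn and counted.
#'
#' @param g a [genotype_matrix()].
#' @param w a harmonized [weight_set()].
#' @param pt a [phenotype_table()].
#' @param phenotype phenotype name with >= 3 measurement waves.
#' @param B bootstrap resamples (>= 100 recommended; fewer warns).
#' @param seed RNG seed for reproducible bands.
#' @param covariate_pcs number of PCs in the association models.
#' @param missing_policy passed to [compute_prs()].
#' @param resample_fun function(n) returning n resample indices;
#'   override for diagnostics (default: iid resampling with
#'   replacement).
#' @return a `trend_result` whose `grid` has `lo95`/`hi95` filled, plus
#'   `B` and `n_redrawn`.
#' @export
bootstrap_trend <- function(g, w, pt, phenotype, B = 200, seed = 1,
                            covariate_pcs = 10,
                            missing_policy = "mean_impute",
                            resample_fun = NULL) {
  if (B < 100) warning("B = ", B, " < 100: bands will be unstable")
  sv <- standardize(compute_prs(g, w, missing_policy))
  pts <- wave_r2_points(sv$standardized, sv$sample_id, pt, phenotype,
                        covariate_pcs)
  base <- fit_trend(pts)
  n <- nrow(sv)
  if (is.null(resample_fun))
    resample_fun <- function(n) sample.int(n, n, replace = TRUE)
  set.seed(seed)
  grid_age <- base$grid$age
  mm_rows <- split(seq_len(nrow(pt$measurements)),
                   pt$measurements$sample_id)
  boot_fit <- matrix(NA_real_, B, length(grid_age))
  n_redrawn <- 0L
  for (b in seq_len(B)) {
    repeat {
      idx <- resample_fun(n)
      raw <- sv$raw[idx]
      if (stats::sd(raw) > 0) break
      n_redrawn <- n_redrawn + 1L
    }
    std <- (raw - mean(raw)) / stats::sd(raw)
    # duplicated ids from resampling: rename so joins stay one-to-one
    bid <- make.unique(sv$sample_id[idx])
    bpt <- resampled_phenotype_table(pt, sv$sample_id[idx], bid, mm_rows)
    bpts <- wave_r2_points(std, bid, bpt, phenotype, covariate_pcs)
    bt <- fit_trend(bpts, grid_length = 2)
    # evaluate the resample's curve on the base grid
    if (bt$df_used >= 2) {
      basis <- splines::ns(bpts$mean_age[order(bpts$mean_age)],
                           df = bt$df_used)
      yb <- bpts$delta_adj_r2[order(bpts$mean_age)]
      cf <- stats::coef(stats::lm(yb ~ basis))
      boot_fit[b, ] <- as.numeric(cbind(1, stats::predict(basis, grid_age))
                                  %*% cf)
    } else {
      boot_fit[b, ] <- bt$slope * grid_age +
        (mean(bpts$delta_adj_r2) - bt$slope * mean(bpts$mean_age))
    }
  }
  qs <- apply(boot_fit, 2, stats::quantile, probs = c(0.025, 0.975),
              names = FALSE)
  base$grid$lo95 <- qs[1, ]
  base$grid$hi95 <- qs[2, ]
  base$B <- B
  base$n_redrawn <- n_redrawn
  base
}

# build a phenotype table for a with-replacement resample of samples;
# mm_rows is split(seq_len(nrow(measurements)), measurements$sample_id)
resampled_phenotype_table <- function(pt, orig_ids, new_ids, mm_rows) {
  ci <- match(orig_ids, pt$covariates$sample_id)
  cov <- pt$covariates[ci, , drop = FALSE]
  cov$sample_id <- new_ids
  picks <- mm_rows[orig_ids]
  rows <- unlist(picks, use.names = FALSE)
  m2 <- pt$measurements[rows, , drop = FALSE]
  m2$sample_id <- rep(new_ids, lengths(picks))
  phenotype_table(cov, m2, pt$phenotype_info)
}

#' Write trend results to TSV
#' @param tr a `trend_result`.
#' @param prefix path prefix; writes `<prefix>_curve.tsv` and
#'   `<prefix>_tests.tsv`.
#' @return `prefix`, invisibly.
#' @export
write_trend <- function(tr, prefix) {
  data.table::fwrite(tr$grid, paste0(prefix, "_curve.tsv"), sep = "\t")
  data.table::fwrite(data.frame(
    df_used = tr$df_used, slope = tr$slope,
    F_linear = tr$F_linear, p_linear = tr$p_linear,
    F_nonlinear = tr$F_nonlinear, p_nonlinear = tr$p_nonlinear),
    paste0(prefix, "_tests.tsv"), sep = "\t")
  invisible(prefix)
}
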