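test_that("fit_linear_assoc recovers the textbook quantities", {
  set.seed(1)
  s <- rnorm(50)
  # perfect fit: y == s, no covariates
  res <- fit_linear_assoc(s, s)
  expect_equal(res$delta_adj_r2_pct, 100, tolerance = 1e-8)
  expect_equal(res$beta, 1, tolerance = 1e-10)

  # against lm() with covariates, including the adjusted-R2 difference
  n <- 300
  cov <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("age", "c1", "c2")))
  s <- rnorm(n)
  y <- 0.3 * s + 0.2 * cov[, 1] + rnorm(n)
  res <- fit_linear_assoc(y, s, cov)
  ref <- summary(lm(y ~ s + cov))
  expect_equal(res$beta, unname(coef(ref)["s", "Estimate"]), tolerance = 1e-10)
  expect_equal(res$se, unname(coef(ref)["s", "Std. Error"]), tolerance = 1e-10)
  expect_equal(res$p, unname(coef(ref)["s", "Pr(>|t|)"]), tolerance = 1e-10)
  expect_equal(res$delta_adj_r2_pct, delta_adj_r2_oracle(y, s, cov),
               tolerance = 1e-10)
  expect_equal(res$n, n)

  # degenerate designs error out
  expect_error(fit_linear_assoc(y, s, cbind(cov, dup = s)), "singular")
  expect_error(fit_linear_assoc(rep(1, n), s, cov), "zero variance")
})

test_that("delta_adj_r2 can be negative and matches the oracle under null", {
  set.seed(2)
  n <- 60
  neg_seen <- FALSE
  for (i in 1:20) {
    y <- rnorm(n); s <- rnorm(n); cov <- matrix(rnorm(n * 2), n, 2)
    res <- fit_linear_assoc(y, s, cov)
    expect_equal(res$delta_adj_r2_pct, delta_adj_r2_oracle(y, s, cov),
                 tolerance = 1e-10)
    if (res$delta_adj_r2_pct < 0) neg_seen <- TRUE
  }
  expect_true(neg_seen)  # unclipped: null fits dip below zero
})

test_that("bh_adjust is the step-up procedure", {
  expect_equal(bh_adjust(0.03), 0.03)                       # m = 1
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))                                # hand-derived
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(3)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-14)
    expect_true(all(q >= p - 1e-15))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-15))                  # monotone
  }
  # agrees with stats::p.adjust as an additional independent reference
  p <- runif(200)
  expect_equal(bh_adjust(p), p.adjust(p, "BH"), tolerance = 1e-14)
})

test_that("run_phewas builds per-PRS BH families and flags q < 0.05", {
  set.seed(4)
  n <- 400
  score <- rnorm(n)
  pt <- make_pt(n, score, beta = 0.25, n_pheno = 6, seed = 4,
                categories = c("substance use", "gambling"))
  sv <- as_score_vector(score, paste0("S", 1:n), "PRS_A")
  res <- run_phewas(list(sv), pt)
  expect_equal(nrow(res), 6)
  expect_equal(res$q, bh_adjust(res$p))           # family = the one PRS
  expect_true(all(res$q >= res$p - 1e-15))
  expect_equal(res$significant, res$q < 0.05)
  expect_true(all(table(res$category) == 3))

  # single PRS x single phenotype: q equals p
  pt1 <- make_pt(n, score, beta = 0.2, n_pheno = 1, seed = 5)
  r1 <- run_phewas(list(sv), pt1)
  expect_equal(r1$q, r1$p)

  # two PRSs adjust independently
  sv2 <- as_score_vector(rnorm(n), paste0("S", 1:n), "PRS_B")
  res2 <- run_phewas(list(sv, sv2), pt)
  expect_equal(res2$q[res2$prs == "PRS_A"],
               bh_adjust(res2$p[res2$prs == "PRS_A"]))
  expect_equal(res2$q[res2$prs == "PRS_B"],
               bh_adjust(res2$p[res2$prs == "PRS_B"]))
})

test_that("age covariate is dropped for age-of-initiation phenotypes", {
  set.seed(6)
  n <- 500
  score <- rnorm(n)
  pt <- make_pt(n, score, beta = 0.2, n_pheno = 2, seed = 6)
  pt$phenotype_info$is_age_of_initiation <- c(FALSE, TRUE)
  # make age strongly predictive so its omission is visible in df/beta
  a <- prsphewas:::assemble_pair(
    as_score_vector(score, paste0("S", 1:n)), pt, "ph01", "w1")
  expect_true("age" %in% colnames(a$cov))
  a2 <- prsphewas:::assemble_pair(
    as_score_vector(score, paste0("S", 1:n)), pt, "ph02", "w1")
  expect_false("age" %in% colnames(a2$cov))
})

test_that("validate_prs retains exactly the q < 0.05 scores", {
  set.seed(7)
  n <- 1200
  true_score <- rnorm(n)
  pt <- make_pt(n, true_score, beta = sqrt(0.03), n_pheno = 1, seed = 7)
  svs <- list(as_score_vector(true_score, paste0("S", 1:n), "PRS_real"),
              as_score_vector(rnorm(n), paste0("S", 1:n), "PRS_noise1"),
              as_score_vector(rnorm(n), paste0("S", 1:n), "PRS_noise2"))
  vm <- data.frame(prs = c("PRS_real", "PRS_noise1", "PRS_noise2"),
                   phenotype = "ph01")
  v <- validate_prs(svs, pt, vm)
  expect_equal(nrow(v), 3)
  expect_equal(v$q, bh_adjust(v$p))      # family = the PRS set
  expect_true(v$retained[v$prs == "PRS_real"])
  expect_error(validate_prs(svs, pt,
                            data.frame(prs = "PRS_real", phenotype = "nope")),
               "absent")
})

test_that("compare_runs reports identity for identical tables", {
  set.seed(8)
  n <- 300
  score <- rnorm(n)
  pt <- make_pt(n, score, beta = 0.2, n_pheno = 5, seed = 8)
  sv <- as_score_vector(score, paste0("S", 1:n))
  a <- run_phewas(list(sv), pt)
  cmp <- compare_runs(a, a)
  expect_equal(cmp$slope, 1, tolerance = 1e-10)
  expect_equal(cmp$r2, 1, tolerance = 1e-10)
  expect_equal(cmp$ci_overlap, 1)
  expect_equal(cmp$n_shared, 5)
  b <- a; b$phenotype <- paste0("other_", b$phenotype)
  expect_error(compare_runs(a, b), "shared")
})
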