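# Independent brute-force oracles. These deliberately recompute the
# statistics by enumeration / naive loops, sharing no code path with
# the package internals they check.

# Exact HWE p by full enumeration: absolute probability of every
# heterozygote configuration with the same allele counts.
hwe_enum_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  na <- n_Aa + 2 * n_aa          # count of the 'a' allele
  hets <- seq(na %% 2, min(na, 2 * n - na), by = 2)
  logprob <- function(h) {
    aa <- (na - h) / 2
    AA <- n - h - aa
    lfactorial(n) + h * log(2) - lfactorial(AA) - lfactorial(h) -
      lfactorial(aa) + lfactorial(na) + lfactorial(2 * n - na) -
      lfactorial(2 * n)
  }
  pr <- exp(vapply(hets, logprob, numeric(1)))
  obs <- pr[hets == n_Aa]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

# Hypergeometric upper tail by counting draws with a Pascal triangle
# (no choose()/phyper): P(X >= k) drawing K from N with m marked.
hyper_enum_oracle <- function(k, m, N, K) {
  pascal <- matrix(0, N + 1, N + 1)
  pascal[, 1] <- 1
  for (i in 2:(N + 1))
    for (j in 2:i) pascal[i, j] <- pascal[i - 1, j - 1] + pascal[i - 1, j]
  cnk <- function(n, r) if (r < 0 || r > n) 0 else pascal[n + 1, r + 1]
  total <- cnk(N, K)
  hits <- 0
  for (x in seq(max(k, 0), min(m, K)))
    hits <- hits + cnk(m, x) * cnk(N - m, K - x)
  hits / total
}

# Textbook BH step-up by explicit double loop.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(j) min(1, p[o[j]] * m / j), numeric(1))
    q[o[i]] <- min(vals)
  }
  q
}

# Naive per-sample, per-variant scoring loop.
naive_prs_oracle <- function(g, w, missing_policy = "mean_impute") {
  ids <- intersect(w$entries$variant_id, g$variants$variant_id)
  n <- nrow(g$dosages)
  raw <- numeric(n)
  for (vid in ids) {
    j <- which(g$variants$variant_id == vid)
    wt <- w$entries$weight[w$entries$variant_id == vid]
    col <- g$dosages[, j]
    mu <- mean(col, na.rm = TRUE)
    for (s in seq_len(n)) {
      d <- col[s]
      if (is.na(d)) {
        if (missing_policy == "mean_impute") d <- mu else next
      }
      raw[s] <- raw[s] + wt * d
    }
  }
  raw
}

# Delta adjusted R2 by two explicit lm() fits.
delta_adj_r2_oracle <- function(y, s, cov = NULL) {
  if (is.null(cov)) {
    full <- summary(lm(y ~ s))
    100 * (full$adj.r.squared - 0)
  } else {
    df <- data.frame(y = y, s = s, cov)
    full <- summary(lm(y ~ ., data = df))
    red <- summary(lm(y ~ . - s, data = df))
    100 * (full$adj.r.squared - red$adj.r.squared)
  }
}
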