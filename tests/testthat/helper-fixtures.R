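# Small in-code fixtures shared across test files.

make_gm <- function(dosages, chrom = NULL, pos = NULL, a1 = NULL,
                    a2 = NULL, info_r2 = NULL) {
  m <- ncol(dosages)
  if (is.null(rownames(dosages)))
    rownames(dosages) <- paste0("S", seq_len(nrow(dosages)))
  if (is.null(colnames(dosages)))
    colnames(dosages) <- paste0("v", seq_len(m))
  genotype_matrix(dosages, data.frame(
    variant_id = colnames(dosages),
    chrom = if (is.null(chrom)) rep("chr1", m) else chrom,
    pos = if (is.null(pos)) seq_len(m) * 100L else pos,
    a1 = if (is.null(a1)) rep("A", m) else a1,
    a2 = if (is.null(a2)) rep("G", m) else a2,
    info_r2 = if (is.null(info_r2)) rep(NA_real_, m) else info_r2,
    stringsAsFactors = FALSE))
}

make_ws <- function(weights, gm, name = "PRS_test") {
  v <- gm$variants
  weight_set(name, data.frame(
    variant_id = v$variant_id, chrom = v$chrom, pos = v$pos,
    effect_allele = v$a1, other_allele = v$a2, weight = weights,
    stringsAsFactors = FALSE))
}

random_gm <- function(n, m, missing_rate = 0, seed = 1) {
  set.seed(seed)
  maf <- runif(m, 0.05, 0.5)
  d <- matrix(rbinom(n * m, 2, rep(maf, each = n)), n, m)
  mode(d) <- "numeric"
  if (missing_rate > 0) d[runif(n * m) < missing_rate] <- NA
  make_gm(d)
}

write_test_vcf <- function(path, ds = TRUE) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
    "##INFO=<ID=R2,Number=1,Type=Float,Description=\"Imputation quality\">",
    "##contig=<ID=chr1>",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           "S1\tS2"))
  fmt <- if (ds) "GT:DS" else "GT"
  rec <- function(pos, id, ref, alt, g1, g2)
    paste("chr1", pos, id, ref, alt, ".", "PASS", "R2=0.95", fmt,
          g1, g2, sep = "\t")
  body <- if (ds) c(
    rec(100, "rs1", "A", "G", "0/1:1.0", "1/1:1.9"),
    rec(200, "rs2", "C", "T", "0/0:0.1", "0/1:0.8"))
  else c(
    rec(100, "rs1", "A", "G", "0/1", "1/1"),
    rec(200, "rs2", "C", "T", "0/0", "./."))
  writeLines(c(hdr, body), path)
  path
}

# small phenotype table with a known linear signal for scan tests
make_pt <- function(n, score, beta = 0.2, n_pheno = 1, seed = 1,
                    categories = "substance use") {
  set.seed(seed)
  ids <- paste0("S", seq_len(n))
  sex <- rbinom(n, 1, 0.5)
  pcs <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("PC", 1:10)))
  meas <- do.call(rbind, lapply(seq_len(n_pheno), function(p) {
    y <- beta * score + rnorm(n, 0, sqrt(max(1e-6, 1 - beta^2)))
    data.frame(sample_id = ids, phenotype = sprintf("ph%02d", p),
               wave = "w1", age = 17 + runif(n), value = y,
               stringsAsFactors = FALSE)
  }))
  info <- data.frame(phenotype = sprintf("ph%02d", seq_len(n_pheno)),
                     category = rep_len(categories, n_pheno),
                     is_age_of_initiation = FALSE)
  phenotype_table(data.frame(sample_id = ids, sex = sex, pcs),
                  meas, info)
}

as_score_vector <- function(std, ids, name = "PRS_test") {
  sv <- data.frame(sample_id = ids, raw = std, standardized = std,
                   stringsAsFactors = FALSE)
  attr(sv, "prs_name") <- name
  attr(sv, "n_snps_used") <- NA_integer_
  class(sv) <- c("score_vector", "data.frame")
  sv
}
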