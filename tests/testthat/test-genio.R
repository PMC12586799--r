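test_that("VCF reading takes DS when present, GT otherwise, keeps order", {
  f <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(f, ds = TRUE)
  g <- read_genotypes(f, "vcf")
  expect_equal(dim(g), c(2L, 2L))
  expect_equal(g$variants$variant_id, c("rs1", "rs2"))
  expect_equal(unname(g$dosages["S1", ]), c(1.0, 0.1))
  expect_equal(unname(g$dosages["S2", ]), c(1.9, 0.8))
  expect_equal(g$variants$a1, c("G", "T"))  # counted allele = ALT
  expect_equal(g$variants$info_r2, c(0.95, 0.95))

  f2 <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(f2, ds = FALSE)
  g2 <- read_genotypes(f2, "vcf")
  expect_equal(unname(g2$dosages["S1", ]), c(1, 0))
  expect_true(is.na(g2$dosages["S2", "rs2"]))  # ./. preserved as missing
})

test_that("multi-allelic VCF records are rejected", {
  f <- withr::local_tempfile(fileext = ".vcf")
  lines <- readLines(write_test_vcf(f, ds = TRUE))
  i <- grep("\trs1\t", lines)
  lines[i] <- sub("\tG\t", "\tG,T\t", lines[i])
  lines[i] <- sub("0/1:1.0", "1/2:1.0", lines[i], fixed = TRUE)
  writeLines(lines, f)
  expect_error(read_genotypes(f, "vcf"), "multi-allelic")
})

test_that("TSV dosage dialect round-trips bit-exactly and keeps NA", {
  g <- random_gm(7, 5, missing_rate = 0.2, seed = 42)
  g$dosages[2, 3] <- 1 / 3   # non-representable decimal
  f <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes_tsv(g, f)
  g2 <- read_genotypes(f, "tsv")
  expect_identical(g2$dosages, g$dosages)
  expect_identical(g2$variants$pos, g$variants$pos)
  expect_true(any(is.na(g2$dosages)))
})

test_that("hwe_exact_test matches enumeration and handles edge tables", {
  expect_equal(hwe_exact_test(50, 0, 0), 1.0)       # monomorphic
  expect_equal(hwe_exact_test(1, 0, 1), 1 / 3)      # two-diploid table
  expect_error(hwe_exact_test(-1, 0, 0), "non-negative")
  # spot panel across sizes and skews (exhaustive sweep in acceptance)
  set.seed(11)
  for (i in 1:200) {
    n <- sample(1:40, 1)
    a <- sample(0:n, 1); h <- sample(0:(n - a), 1); b <- n - a - h
    expect_equal(hwe_exact_test(a, h, b), hwe_enum_oracle(a, h, b),
                 tolerance = 1e-12)
  }
})

test_that("qc_filter applies each rule strictly and partitions variants", {
  set.seed(2)
  n <- 400
  d <- cbind(
    rare = rbinom(n, 2, 0.005),           # MAF below floor
    common = rbinom(n, 2, 0.3),           # passes everything
    gappy = rbinom(n, 2, 0.3),
    offhwe = c(rep(0, n / 2), rep(2, n / 2)),  # all homozygote: HWE fails
    lowinfo = rbinom(n, 2, 0.3))
  d <- matrix(as.numeric(d), n, 5, dimnames = list(paste0("S", 1:n),
                                                   colnames(d)))
  d[1:10, 3] <- NA                         # 2.5% missing: below the cap
  g <- make_gm(d, info_r2 = c(NA, NA, NA, NA, 0.2))
  out <- qc_filter(g, qc_thresholds())
  expect_setequal(out$genotypes$variants$variant_id, c("common", "gappy"))
  rep <- out$report
  expect_equal(nrow(rep), 5)
  expect_equal(sum(rep$pass) + sum(!rep$pass), 5)
  expect_match(rep$failed_rules[rep$variant_id == "rare"], "maf")
  expect_match(rep$failed_rules[rep$variant_id == "offhwe"], "hwe")
  expect_match(rep$failed_rules[rep$variant_id == "lowinfo"], "info_r2")

  # idempotence: re-filtering removes nothing
  out2 <- qc_filter(out$genotypes, qc_thresholds())
  expect_equal(dim(out2$genotypes), dim(out$genotypes))

  # MAF 0.005 with the default threshold is removed; all-fail errors
  expect_error(qc_filter(make_gm(matrix(c(0, 0, 0, 0), 4, 1)),
                         qc_thresholds()), "empty after QC")
})

test_that("harmonize_weights reconciles alleles, strands and ambiguity", {
  g <- make_gm(matrix(1, 1, 4), pos = c(100L, 200L, 300L, 400L),
               a1 = c("A", "C", "C", "A"), a2 = c("G", "A", "A", "T"))
  w <- weight_set("w", data.frame(
    variant_id = paste0("x", 1:4),         # ids differ: match is by pos
    chrom = "chr1", pos = c(100L, 200L, 300L, 400L),
    effect_allele = c("A", "A", "G", "A"),
    other_allele = c("G", "C", "T", "T"),
    weight = c(0.5, 0.3, 0.2, 0.7), stringsAsFactors = FALSE))
  h <- harmonize_weights(w, g$variants)
  e <- h$entries
  # x1: direct match, weight kept
  expect_equal(e$weight[e$pos == 100], 0.5)
  # x2: effect allele equals a2 -> negated
  expect_equal(e$weight[e$pos == 200], -0.3)
  # x3: (G,T) vs (C,A) matches via strand complement
  expect_equal(e$weight[e$pos == 300], 0.2)
  # x4: A/T ambiguous -> dropped by default
  expect_false(400 %in% e$pos)
  expect_equal(attr(h, "log")$reason, "strand_ambiguous")
  # with drop_ambiguous = FALSE the A/T variant is retained
  h2 <- harmonize_weights(w, g$variants, drop_ambiguous = FALSE)
  expect_true(400 %in% h2$entries$pos)
  # no strand flip allowed -> x3 drops as mismatch
  h3 <- harmonize_weights(w, g$variants, allow_strand_flip = FALSE)
  expect_false(300 %in% h3$entries$pos)
  # zero matches is an error
  w_far <- weight_set("w", transform(w$entries, pos = pos + 5L))
  expect_error(harmonize_weights(w_far, g$variants), "zero variants")
})

test_that("gene models read from BED and GFF3 agree in 1-based coords", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t99\t200\tgeneX\t0\t+", bed)
  gb <- read_gene_models(bed)
  expect_equal(gb$start, 100)   # 0-based half-open converted
  expect_equal(gb$end, 200)
  expect_equal(gb$gene_id, "geneX")

  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t100\t200\t.\t+\t.\tID=geneX"), gff)
  gg <- read_gene_models(gff)
  expect_equal(gg[, c("chrom", "start", "end")],
               gb[, c("chrom", "start", "end")])
})

test_that("GMT parsing de-duplicates and flags empty sets", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg2\tg3",
               "setB\tdesc"), f)
  expect_warning(sets <- read_gmt(f), "empty")
  expect_equal(sets$setA, c("g1", "g2", "g3"))
  expect_length(sets$setB, 0)
})

test_that("gmt and gff3 writers round-trip through the readers", {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = c("chr1", "chr2"),
                      start = c(100L, 5000L), end = c(900L, 9000L))
  sets <- list(p1 = c("g1", "g2"), p2 = "g2")
  gff <- withr::local_tempfile(fileext = ".gff3")
  gmt <- withr::local_tempfile(fileext = ".gmt")
  write_gene_models_gff3(genes, gff)
  write_gmt(sets, gmt)
  g2 <- read_gene_models(gff)
  expect_equal(g2$gene_id, genes$gene_id)
  expect_equal(g2$start, genes$start)
  expect_equal(g2$end, genes$end)
  expect_equal(read_gmt(gmt), sets)
})
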