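test_that("SNP-to-gene window mapping is inclusive at the boundary", {
  genes <- data.frame(gene_id = c("gA", "gB", "gC"),
                      chrom = c("chr1", "chr1", "chr2"),
                      start = c(200000L, 360000L, 200000L),
                      end = c(300000L, 460000L, 300000L))
  v <- data.frame(
    variant_id = c("in50kb", "at100kb", "past100kb", "overlap2", "wrongchr"),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr1"),
    pos = c(150000L, 100000L, 99999L, 260000L, 250000L))
  v$chrom[5] <- "chr3"
  mp <- map_snps_to_genes(v, genes, 100000)
  sets <- split(mp$map$gene_id, mp$map$variant_id)
  expect_equal(sets$in50kb, "gA")                 # 50 kb upstream
  expect_equal(sets$at100kb, "gA")                # exactly 100 kb: mapped
  expect_false("past100kb" %in% names(sets))      # 100,001 bp: not mapped
  expect_setequal(sets$overlap2, c("gA", "gB"))   # multi-mapping
  expect_true("wrongchr" %in% mp$unmapped)
  expect_equal(mp$map$distance_bp[mp$map$variant_id == "at100kb"], 100000)
  expect_error(map_snps_to_genes(v, genes, -1), "non-negative")
})

test_that("mapping inverts consistently between SNP and gene views", {
  set.seed(1)
  genes <- data.frame(gene_id = paste0("g", 1:10), chrom = "chr1",
                      start = (1:10) * 300000L,
                      end = (1:10) * 300000L + 20000L)
  v <- data.frame(variant_id = paste0("s", 1:60), chrom = "chr1",
                  pos = sort(sample.int(3500000L, 60)))
  mp <- map_snps_to_genes(v, genes, 100000)
  pairs_fwd <- paste(mp$map$variant_id, mp$map$gene_id)
  by_gene <- split(mp$map$variant_id, mp$map$gene_id)
  pairs_inv <- unlist(lapply(names(by_gene), function(gid)
    paste(by_gene[[gid]], gid)))
  expect_setequal(pairs_fwd, pairs_inv)
})

test_that("hypergeometric enrichment equals the enumeration oracle", {
  # the fully-contained case has the closed form 1/choose(20, 5)
  expect_equal(prsphewas:::hypergeom_upper(5, 5, 20, 5), 1 / choose(20, 5),
               tolerance = 1e-12)
  expect_equal(prsphewas:::hypergeom_upper(0, 5, 20, 5), 1)  # k = 0
  set.seed(2)
  for (i in 1:150) {
    N <- sample(2:25, 1)
    m <- sample(0:N, 1)
    K <- sample(0:N, 1)
    k <- sample(0:min(m, K), 1)
    expect_equal(prsphewas:::hypergeom_upper(k, m, N, K),
                 hyper_enum_oracle(k, m, N, K), tolerance = 1e-12)
  }
})

test_that("enrich_pathways counts unique genes and adjusts across sets", {
  mapped <- paste0("g", 1:5)
  background <- paste0("g", 1:20)
  pws <- list(all_in = paste0("g", 1:5),
              disjoint = paste0("g", 10:14),
              half = paste0("g", c(1, 2, 15, 16)))
  res <- enrich_pathways(mapped, pws, background = background)
  expect_equal(res$p[res$pathway == "all_in"], 1 / choose(20, 5),
               tolerance = 1e-12)
  expect_equal(res$p[res$pathway == "disjoint"], 1)    # k = 0
  expect_equal(res$q, bh_adjust(res$p))  # rows arrive sorted by p
  expect_true(res$enriched[res$pathway == "all_in"])
  expect_error(enrich_pathways(character(0), pws, background), "empty")
})

test_that("eligibility requires >1% variance and hits in every category", {
  tab <- data.frame(
    prs = rep(c("strong", "weak", "patchy"), each = 4),
    category = rep(c("a", "b", "c", "d"), 3),
    q = c(rep(0.01, 4), rep(0.01, 4), c(0.01, 0.01, 0.01, 0.5)),
    delta_adj_r2_pct = c(4.7, 2, 1.5, 1.2, 0.9, 0.5, 0.4, 0.3,
                         3, 2, 1.5, 1.2))
  expect_equal(select_partition_eligible(tab), "strong")
  # 0.9% max: excluded despite all-category hits; patchy misses category d
  expect_false("weak" %in% select_partition_eligible(tab))
  expect_false("patchy" %in% select_partition_eligible(tab))
})

test_that("partitioned scores respect assignment, overlap and linearity", {
  set.seed(3)
  g <- random_gm(120, 30, seed = 3)
  g$variants$pos <- (1:30) * 300000L
  wts <- rnorm(30) * rbinom(30, 1, 0.7)
  w <- make_ws(wts, g)
  genes <- data.frame(gene_id = paste0("g", 1:30), chrom = "chr1",
                      start = (1:30) * 300000L - 5000L,
                      end = (1:30) * 300000L + 5000L)
  mp <- map_snps_to_genes(g$variants, genes, 50000)
  pws <- list(first = paste0("g", 1:15), second = paste0("g", 16:30),
              both = paste0("g", 14:17), empty_pw = "gX")
  part <- suppressWarnings(
    build_partitioned_scores(w, mp, names(pws), pws, g))
  expect_false("empty_pw" %in% names(part))   # zero assigned SNPs skipped

  # each partition equals the score of {non-zero weights} ∩ {SNPs
  # mapped to that pathway's genes} — zero-weight SNPs never enter
  nz <- w$entries$variant_id[w$entries$weight != 0]
  for (nm in names(part)) {
    vids <- intersect(nz,
                      unique(mp$map$variant_id[mp$map$gene_id %in% pws[[nm]]]))
    ref <- standardize(compute_prs(g, restrict_weights(w, vids)))
    expect_equal(part[[nm]]$standardized, ref$standardized,
                 tolerance = 1e-10)
  }

  # disjoint partitions sum to the mapped-subset raw score
  mapped_nz <- intersect(nz, unique(mp$map$variant_id))
  full_raw <- compute_prs(g, restrict_weights(w, mapped_nz))$raw
  raw_sum <- compute_prs(g, restrict_weights(
    w, intersect(mapped_nz,
                 mp$map$variant_id[mp$map$gene_id %in% pws$first])))$raw +
    compute_prs(g, restrict_weights(
      w, intersect(mapped_nz,
                   mp$map$variant_id[mp$map$gene_id %in% pws$second])))$raw
  expect_equal(raw_sum, full_raw, tolerance = 1e-10)

  # a SNP whose gene is in two pathways contributes to both
  shared_genes <- intersect(pws$both, pws$first)
  shared_snps <- unique(mp$map$variant_id[mp$map$gene_id %in% shared_genes])
  shared_nz <- intersect(shared_snps, nz)
  expect_gt(length(shared_nz), 0)
})

test_that("a planted enriched pathway is found and wins the re-scan", {
  cfg <- sim_config(n_samples = 700, n_variants = 250,
                    missing_rate = 0, ages = 17,
                    target_r2 = 0.05, planted_pathway = "planted",
                    concentration = Inf, weight_sparsity = 0.15,
                    seed = 17)
  ann <- gen_annotation(cfg)
  g <- gen_genotypes(cfg, ann)
  w <- gen_weights(cfg, g, ann)
  pt <- gen_phenotypes(g, w, cfg)
  nz <- w$entries[w$entries$weight != 0, ]
  mp <- map_snps_to_genes(nz, ann$genes, cfg$window_bp)
  enr <- enrich_pathways(mp, ann$pathways, genes = ann$genes)
  expect_equal(enr$pathway[1], "planted")      # ranks first by p
  expect_true(enr$enriched[1])

  sv <- standardize(compute_prs(g, w))
  part <- suppressWarnings(build_partitioned_scores(
    w, mp, enr$pathway[enr$q < 0.5], ann$pathways, g))
  pa <- run_partitioned_phewas(part, pt)
  best <- pa$prs[which.max(pa$delta_adj_r2_pct)]
  expect_match(best, "planted")                # all true effects inside
})
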