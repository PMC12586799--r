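# Seeded synthetic-data generator: genotypes in Hardy-Weinberg
# proportions, a toy annotated genome with a planted enriched pathway,
# sparse weight vectors, and longitudinal phenotypes with a configured
# variance-explained trajectory. Ground truth is returned alongside so
# every pipeline stage has a parameter-recovery target.

#' Simulation configuration
#'
#' Defaults describe the desk-scale world the test-suite exercises:
#' 4000 unrelated samples, 300 independent SNPs with MAF uniform on
#' [0.01, 0.5], 1% missingness, a weight vector with 30% non-zero
#' entries, a score explaining a constant 3% of phenotype variance
#' across five waves at mean ages 16-28 (the magnitude range typical of
#' well-powered behavioural PRSs), a small sex main effect and no sex
#' interaction unless requested.
#'
#' @param n_samples samples.
#' @param n_variants variants.
#' @param maf_range MAF drawn uniformly from this interval.
#' @param missing_rate per-entry missingness, completely at random.
#' @param weight_sparsity fraction of variants with non-zero weight.
#' @param target_r2 variance explained by the true score (constant
#'   trajectory).
#' @param sex_effect per-SD sex main effect on the phenotype.
#' @param sex_interaction_effect score-by-sex coefficient (male minus
#'   female difference in the per-SD score effect, sex coded 0/1).
#' @param pc_effect coefficient shared by the 10 simulated PCs.
#' @param ages wave mean ages, strictly increasing.
#' @param r2_trajectory list: `type` in `{"constant",
#'   "linear_decline", "quadratic"}` plus parameters (`r2` for constant,
#'   `r2_start`/`r2_end` for linear decline between the first and last
#'   age, `r2_edge`/`r2_mid` for a quadratic with vertex at the middle
#'   age).
#' @param n_phenotypes number of phenotypes (independent noise).
#' @param r2_per_phenotype optional per-phenotype variance-explained
#'   overrides (recycled); `0` gives a pure-null phenotype.
#' @param categories category labels cycled over phenotypes.
#' @param n_genes,gene_width_bp,gene_spacing_bp toy genome layout (two
#'   chromosomes; two extra overlapping genes are always added).
#' @param n_pathways,pathway_size random gene-set count and size.
#' @param planted_pathway id of the planted enriched set, or NULL.
#' @param planted_size genes in the planted set.
#' @param concentration how many times likelier a non-zero weight is
#'   for SNPs mapped to planted-pathway genes; `Inf` puts all non-zero
#'   weights inside the planted pathway.
#' @param window_bp SNP-to-gene window used when planting.
#' @param frac_intergenic fraction of variants placed far from genes.
#' @param seed RNG seed governing every draw.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 4000, n_variants = 300,
                       maf_range = c(0.01, 0.5), missing_rate = 0.01,
                       weight_sparsity = 0.3, target_r2 = 0.03,
                       sex_effect = 0.1, sex_interaction_effect = 0,
                       pc_effect = 0.02,
                       ages = c(16, 19, 22, 25, 28),
                       r2_trajectory = list(type = "constant"),
                       n_phenotypes = 1, r2_per_phenotype = NULL,
                       categories = c("substance use", "gambling",
                                      "eating", "internet use"),
                       n_genes = 60, gene_width_bp = 20000,
                       gene_spacing_bp = 250000,
                       n_pathways = 10, pathway_size = 8,
                       planted_pathway = NULL, planted_size = 12,
                       concentration = 5, window_bp = 100000,
                       frac_intergenic = 0.15, seed = 1) {
  stopifnot(missing_rate >= 0, missing_rate <= 1,
            weight_sparsity >= 0, weight_sparsity <= 1,
            target_r2 >= 0, target_r2 < 1,
            all(diff(ages) > 0))
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

# the configured variance-explained trajectory as a function of age
trajectory_fun <- function(cfg) {
  tr <- cfg$r2_trajectory
  a0 <- min(cfg$ages); a1 <- max(cfg$ages)
  switch(tr$type,
    constant = {
      r2 <- if (!is.null(tr$r2)) tr$r2 else cfg$target_r2
      function(age) rep(r2, length(age))
    },
    linear_decline = {
      rs <- if (!is.null(tr$r2_start)) tr$r2_start else 0.04
      re <- if (!is.null(tr$r2_end)) tr$r2_end else 0.01
      function(age) rs + (re - rs) * (age - a0) / (a1 - a0)
    },
    quadratic = {
      edge <- if (!is.null(tr$r2_edge)) tr$r2_edge else 0.04
      mid <- if (!is.null(tr$r2_mid)) tr$r2_mid else 0.01
      ctr <- (a0 + a1) / 2
      function(age) mid + (edge - mid) * ((age - ctr) / (a1 - ctr))^2
    },
    stop("unknown trajectory type: ", tr$type))
}

#' Generate a toy annotated genome
#'
#' Two chromosomes of regularly spaced non-overlapping genes (spacing
#' wide enough that default SNP windows do not bridge neighbours), plus
#' two deliberately overlapping genes; random pathways as gene sets and,
#' when configured, the planted pathway as a fixed random subset of
#' genes.
#'
#' @param cfg a [sim_config()].
#' @return list with `genes` (data.frame as from [read_gene_models()])
#'   and `pathways` (named list of gene-id vectors).
#' @export
gen_annotation <- function(cfg) {
  set.seed(cfg$seed + 1L)
  n <- cfg$n_genes
  per_chr <- ceiling(n / 2)
  idx <- seq_len(n)
  chrom <- ifelse(idx <= per_chr, "chr1", "chr2")
  within <- ifelse(idx <= per_chr, idx, idx - per_chr)
  start <- 50000 + (within - 1) * cfg$gene_spacing_bp
  genes <- data.frame(gene_id = sprintf("gene%03d", idx),
                      chrom = chrom, start = start,
                      end = start + cfg$gene_width_bp - 1,
                      stringsAsFactors = FALSE)
  # two genes overlapping the first gene of each chromosome
  ov <- data.frame(
    gene_id = c("geneOVL1", "geneOVL2"),
    chrom = c("chr1", "chr2"),
    start = genes$start[c(1, per_chr + 1)] + cfg$gene_width_bp %/% 2,
    end = genes$start[c(1, per_chr + 1)] + cfg$gene_width_bp %/% 2 +
      cfg$gene_width_bp - 1,
    stringsAsFactors = FALSE)
  genes <- rbind(genes, ov)
  universe <- genes$gene_id
  pathways <- lapply(seq_len(cfg$n_pathways), function(i)
    sort(sample(universe, min(cfg$pathway_size, length(universe)))))
  names(pathways) <- sprintf("pathway%02d", seq_len(cfg$n_pathways))
  if (!is.null(cfg$planted_pathway)) {
    pathways[[cfg$planted_pathway]] <-
      sort(sample(universe, min(cfg$planted_size, length(universe))))
  }
  list(genes = genes, pathways = pathways)
}

#' Generate genotype dosages in Hardy-Weinberg proportions
#'
#' Each variant's MAF is uniform on `maf_range`; dosages are binomial
#' draws of two alleles (independent variants, no LD). Missing entries
#' are injected completely at random. When an annotation is supplied,
#' variants are placed inside gene windows (a `frac_intergenic` share is
#' placed in gene-free gaps) so SNP-to-gene mapping is exercised;
#' otherwise positions are sequential on one chromosome.
#'
#' @param cfg a [sim_config()].
#' @param annotation optional output of [gen_annotation()].
#' @return a [genotype_matrix()]; attribute `"maf"` carries the true
#'   per-variant MAFs.
#' @export
gen_genotypes <- function(cfg, annotation = NULL) {
  set.seed(cfg$seed + 2L)
  n <- cfg$n_samples; m <- cfg$n_variants
  maf <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
  d <- matrix(stats::rbinom(n * m, 2L, rep(maf, each = n)), n, m)
  mode(d) <- "numeric"
  if (cfg$missing_rate > 0) {
    miss <- stats::runif(n * m) < cfg$missing_rate
    d[miss] <- NA_real_
  }
  alleles <- c("A", "C", "G", "T")
  a2 <- sample(alleles, m, replace = TRUE)
  a1 <- vapply(a2, function(x) sample(setdiff(alleles, x), 1), "")
  if (is.null(annotation)) {
    chrom <- rep("chr1", m)
    pos <- seq_len(m) * 1000L
  } else {
    genes <- annotation$genes
    n_inter <- round(cfg$frac_intergenic * m)
    host <- sample(nrow(genes), m - n_inter, replace = TRUE)
    gpos <- round(stats::runif(m - n_inter,
                               genes$start[host] - cfg$window_bp / 2,
                               genes$end[host] + cfg$window_bp / 2))
    gpos <- pmax(1, gpos)
    # intergenic: beyond every gene window on chr1
    far0 <- max(genes$end[genes$chrom == "chr1"]) + cfg$window_bp * 2
    ipos <- far0 + seq_len(n_inter) * 1000L
    chrom <- c(genes$chrom[host], rep("chr1", n_inter))
    pos <- c(gpos, ipos)
  }
  variants <- data.frame(
    variant_id = sprintf("snp%05d", seq_len(m)),
    chrom = chrom, pos = pos, a1 = unname(a1), a2 = a2,
    info_r2 = NA_real_, stringsAsFactors = FALSE)
  rownames(d) <- sprintf("S%05d", seq_len(n))
  g <- genotype_matrix(d, variants)
  attr(g, "maf") <- maf
  g
}

#' Generate a sparse weight vector
#'
#' `weight_sparsity` of the variants receive standard-normal weights,
#' the rest are exactly zero. With a planted pathway, SNPs mappable to
#' its genes (within `window_bp`) are `concentration` times likelier to
#' receive a non-zero weight, with the background rate solved so the
#' overall expected sparsity is preserved; `concentration = Inf` puts
#' every non-zero weight inside the pathway.
#'
#' @param cfg a [sim_config()].
#' @param g a [genotype_matrix()] from [gen_genotypes()].
#' @param annotation required when `cfg$planted_pathway` is set.
#' @return a [weight_set()] named `"PRS_sim"`, effect allele = `a1`.
#' @export
gen_weights <- function(cfg, g, annotation = NULL) {
  set.seed(cfg$seed + 3L)
  if (cfg$weight_sparsity == 0)
    stop("weight_sparsity = 0 would produce a degenerate (all-zero) score")
  m <- nrow(g$variants)
  if (is.null(cfg$planted_pathway)) {
    prob <- rep(cfg$weight_sparsity, m)
    planted_snps <- character(0)
  } else {
    if (is.null(annotation))
      stop("annotation required when planted_pathway is set")
    pw_genes <- annotation$pathways[[cfg$planted_pathway]]
    map <- map_snps_to_genes(g$variants, annotation$genes, cfg$window_bp)
    planted_snps <- unique(map$map$variant_id[map$map$gene_id %in% pw_genes])
    inside <- g$variants$variant_id %in% planted_snps
    n_p <- sum(inside)
    if (is.infinite(cfg$concentration)) {
      r_b <- 0
      r_p <- min(1, cfg$weight_sparsity * m / max(n_p, 1))
    } else {
      r_b <- cfg$weight_sparsity * m /
        (m + (cfg$concentration - 1) * n_p)
      r_p <- min(1, cfg$concentration * r_b)
    }
    prob <- ifelse(inside, r_p, r_b)
  }
  nz <- stats::runif(m) < prob
  if (!any(nz)) nz[sample(which(prob > 0), 1)] <- TRUE
  weight <- ifelse(nz, stats::rnorm(m), 0)
  v <- g$variants
  w <- weight_set("PRS_sim", data.frame(
    variant_id = v$variant_id, chrom = v$chrom, pos = v$pos,
    effect_allele = v$a1, other_allele = v$a2, weight = weight,
    stringsAsFactors = FALSE))
  attr(w, "planted_snps") <- planted_snps
  w
}

#' Generate longitudinal phenotypes with known variance explained
#'
#' The true score is the standardized PRS of `w` over `g`. For each
#' phenotype and wave at age `a`,
#' `y = beta(a) * score + gamma * sex + delta * sex * score +
#'  sum_j c * PC_j + eps`, with `beta(a) = sqrt(r2(a))` and the residual
#' variance chosen so the total phenotype variance is 1 — the
#' population delta adjusted R2 of the score then equals `r2(a)`.
#' Sex is Bernoulli(0.5) coded 0/1; PCs are independent standard
#' normals; ages are jittered +/- 0.5 y around the wave mean.
#'
#' @param g a [genotype_matrix()].
#' @param w a [weight_set()].
#' @param cfg a [sim_config()].
#' @return a [phenotype_table()]; attribute `"truth"` records the
#'   per-wave `beta`, target r2 and the standardized true score.
#' @export
gen_phenotypes <- function(g, w, cfg) {
  force(g); force(w)   # lazy args may seed their own RNG streams
  set.seed(cfg$seed + 4L)
  n <- nrow(g$dosages)
  ids <- rownames(g$dosages)
  score <- if (all(w$entries$weight == 0)) rep(0, n)
           else standardize(compute_prs(g, w, "mean_impute"))$standardized
  sex <- stats::rbinom(n, 1, 0.5)
  pcs <- matrix(stats::rnorm(n * 10), n, 10,
                dimnames = list(NULL, paste0("PC", 1:10)))
  traj <- trajectory_fun(cfg)
  r2pp <- if (is.null(cfg$r2_per_phenotype)) NULL
          else rep_len(cfg$r2_per_phenotype, cfg$n_phenotypes)
  gam <- cfg$sex_effect; del <- cfg$sex_interaction_effect
  cpc <- cfg$pc_effect
  pc_part <- as.numeric(pcs %*% rep(cpc, 10))
  meas <- list(); truth <- list()
  for (p in seq_len(cfg$n_phenotypes)) {
    pname <- sprintf("pheno%02d", p)
    for (t in seq_along(cfg$ages)) {
      a <- cfg$ages[t]
      r2 <- if (is.null(r2pp)) traj(a) else r2pp[p] * (traj(a) / traj(cfg$ages[1]))
      if (r2 >= 1) stop("requested variance explained >= 1 at age ", a)
      beta <- sqrt(r2)
      var_rest <- 1 - r2 - gam^2 * 0.25 - del^2 * 0.5 - 10 * cpc^2
      if (var_rest <= 0)
        stop("variance budget exceeded: reduce effect sizes")
      eps <- stats::rnorm(n, 0, sqrt(var_rest))
      age_i <- a + stats::runif(n, -0.5, 0.5)
      y <- beta * score + gam * sex + del * sex * score + pc_part + eps
      meas[[length(meas) + 1L]] <- data.frame(
        sample_id = ids, phenotype = pname, wave = paste0("w", t),
        age = age_i, value = y, stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- data.frame(
        phenotype = pname, wave = paste0("w", t), age = a,
        beta = beta, r2 = r2, stringsAsFactors = FALSE)
    }
  }
  info <- data.frame(
    phenotype = sprintf("pheno%02d", seq_len(cfg$n_phenotypes)),
    category = rep_len(cfg$categories, cfg$n_phenotypes),
    is_age_of_initiation = FALSE, stringsAsFactors = FALSE)
  cov <- data.frame(sample_id = ids, sex = sex, pcs,
                    stringsAsFactors = FALSE)
  pt <- phenotype_table(cov, do.call(rbind, meas), info)
  attr(pt, "truth") <- list(waves = do.call(rbind, truth),
                            score = score,
                            sex_effect = gam,
                            sex_interaction_effect = del)
  pt
}

#' Write a complete synthetic fixture directory
#'
#' Emits genotypes (TSV dialect), weights, phenotype covariates and
#' measurements, annotation (GFF3 + GMT) and `truth.json` with every
#' planted parameter — all plain text, fully determined by `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created).
#' @return `dir`, invisibly; the generated objects as attribute
#'   `"objects"`.
#' @export
simulate_dataset <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ann <- gen_annotation(cfg)
  g <- gen_genotypes(cfg, ann)
  w <- gen_weights(cfg, g, ann)
  pt <- gen_phenotypes(g, w, cfg)
  write_genotypes_tsv(g, file.path(dir, "genotypes.tsv"))
  write_weights(w, file.path(dir, "weights.tsv"))
  data.table::fwrite(pt$covariates, file.path(dir, "covariates.tsv"),
                     sep = "\t", quote = FALSE)
  data.table::fwrite(pt$measurements, file.path(dir, "measurements.tsv"),
                     sep = "\t", quote = FALSE)
  data.table::fwrite(pt$phenotype_info, file.path(dir, "phenotype_info.tsv"),
                     sep = "\t", quote = FALSE)
  write_gene_models_gff3(ann$genes, file.path(dir, "genes.gff3"))
  write_gmt(ann$pathways, file.path(dir, "pathways.gmt"))
  truth <- attr(pt, "truth")
  jsonlite::write_json(
    list(seed = cfg$seed, n_samples = cfg$n_samples,
         n_variants = cfg$n_variants, target_r2 = cfg$target_r2,
         sex_effect = truth$sex_effect,
         sex_interaction_effect = truth$sex_interaction_effect,
         waves = truth$waves,
         planted_pathway = cfg$planted_pathway),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  out <- invisible(dir)
  attr(out, "objects") <- list(annotation = ann, genotypes = g,
                               weights = w, phenotypes = pt)
  out
}

#' Read a phenotype table from a fixture directory
#' @param dir directory written by [simulate_dataset()].
#' @return a [phenotype_table()].
#' @export
read_phenotypes_dir <- function(dir) {
  cov <- data.table::fread(file.path(dir, "covariates.tsv"),
                           data.table = FALSE)
  mm <- data.table::fread(file.path(dir, "measurements.tsv"),
                          data.table = FALSE)
  info <- data.table::fread(file.path(dir, "phenotype_info.tsv"),
                            data.table = FALSE)
  phenotype_table(cov, mm, info)
}
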