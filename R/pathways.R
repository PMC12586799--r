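# Pathway partitioning: SNP-to-gene window mapping, hypergeometric
# over-representation, pathway-restricted score construction and re-scan.

#' Select PRSs eligible for pathway partitioning
#'
#' A PRS qualifies when it shows some explanatory power — maximum
#' delta adjusted R2 above `min_r2_pct` — and a significant association
#' (`q < alpha`) in every phenotype category.
#'
#' @param phewas_results `assoc_table` from [run_phewas()] with
#'   non-trivial `category` labels.
#' @param min_r2_pct variance-explained floor, percent (default 1).
#' @param alpha FDR threshold (default 0.05).
#' @return character vector of eligible PRS names (possibly empty).
#' @export
select_partition_eligible <- function(phewas_results, min_r2_pct = 1,
                                      alpha = 0.05) {
  res <- as.data.frame(phewas_results)
  cats <- unique(res$category)
  if (length(cats) == 0 || all(is.na(cats)))
    stop("no phenotype categories defined")
  keep <- vapply(unique(res$prs), function(prs) {
    r <- res[res$prs == prs, , drop = FALSE]
    if (max(r$delta_adj_r2_pct, na.rm = TRUE) <= min_r2_pct) return(FALSE)
    hits <- unique(r$category[r$q < alpha])
    all(cats %in% hits)
  }, logical(1))
  names(keep)[keep]
}

#' Map non-zero-weight SNPs to genes within a window
#'
#' A variant maps to every gene whose interval, extended by `window_bp`
#' on both sides, covers its position on the same chromosome
#' (inclusive at exactly `window_bp`). Multi-mapping is expected: one
#' SNP can feed several genes and hence several pathway scores.
#'
#' @param variants data.frame with `variant_id`, `chrom`, `pos` — only
#'   non-zero-weight variants should be passed.
#' @param genes gene models from [read_gene_models()].
#' @param window_bp window in base pairs (default 100000).
#' @return object of class `snp_gene_map`: list with `map` (data.frame
#'   `variant_id`, `gene_id`, `distance_bp`), `unmapped` (variant ids),
#'   `window_bp`.
#' @export
map_snps_to_genes <- function(variants, genes, window_bp = 100000) {
  if (window_bp < 0) stop("window_bp must be non-negative")
  vr <- GenomicRanges::GRanges(
    variants$chrom, IRanges::IRanges(variants$pos, variants$pos))
  ext_start <- pmax(1, genes$start - window_bp)
  gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(ext_start, genes$end + window_bp))
  # chromosomes present on one side only are simply non-overlapping
  ov <- suppressWarnings(GenomicRanges::findOverlaps(vr, gr))
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  pos <- variants$pos[qi]
  dist <- pmax(0, pmax(genes$start[si] - pos, pos - genes$end[si]))
  map <- data.frame(variant_id = variants$variant_id[qi],
                    gene_id = genes$gene_id[si],
                    distance_bp = dist, stringsAsFactors = FALSE)
  unmapped <- setdiff(variants$variant_id, map$variant_id)
  structure(list(map = map, unmapped = unmapped, window_bp = window_bp),
            class = "snp_gene_map")
}

#' @export
print.snp_gene_map <- function(x, ...) {
  cat("snp_gene_map:", length(unique(x$map$variant_id)), "variants ->",
      length(unique(x$map$gene_id)), "genes (window",
      x$window_bp, "bp);", length(x$unmapped), "unmapped\n")
  invisible(x)
}

#' Pathway over-representation of mapped genes
#'
#' One-sided hypergeometric upper-tail test per pathway on unique gene
#' counts: with `N` background genes of which `K` are mapped, a pathway
#' of size `m` (within background) containing `k` mapped genes has
#' `p = P(X >= k)` for `X ~ Hypergeom(N, m, K)`. BH adjustment across
#' pathways; enriched iff `q < alpha`.
#'
#' @param map a `snp_gene_map` (or character vector of mapped gene ids).
#' @param pathways named list of gene-id vectors ([read_gmt()]).
#' @param background background gene universe; defaults to all genes in
#'   the annotation if `genes` given, else the union of pathway genes.
#' @param genes optional gene models supplying the default background.
#' @param alpha enrichment FDR threshold (default 0.01).
#' @return data.frame: `pathway`, `k`, `m`, `K`, `N`, `p`, `q`,
#'   `enriched`, sorted by `p`.
#' @export
enrich_pathways <- function(map, pathways, background = NULL,
                            genes = NULL, alpha = 0.01) {
  mapped <- if (inherits(map, "snp_gene_map")) unique(map$map$gene_id)
            else unique(map)
  if (length(mapped) == 0) stop("empty mapped-gene set")
  if (is.null(background)) {
    background <- if (!is.null(genes)) unique(genes$gene_id)
                  else unique(unlist(pathways))
  }
  background <- unique(background)
  mapped <- intersect(mapped, background)
  N <- length(background); K <- length(mapped)
  rows <- lapply(names(pathways), function(nm) {
    pw <- intersect(unique(pathways[[nm]]), background)
    m <- length(pw)
    k <- length(intersect(pw, mapped))
    p <- hypergeom_upper(k, m, N, K)
    data.frame(pathway = nm, k = k, m = m, K = K, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q <- bh_adjust(res$p)
  res$enriched <- res$q < alpha
  res[order(res$p, res$pathway), , drop = FALSE]
}

# P(X >= k) for X ~ Hypergeom(N total, m marked, K drawn)
hypergeom_upper <- function(k, m, N, K) {
  if (k <= 0) return(1)
  stats::phyper(k - 1, m, N - m, K, lower.tail = FALSE)
}

#' Build pathway-partitioned scores
#'
#' For each enriched pathway, restricts the weight set to the non-zero-
#' weight variants whose mapped gene set intersects that pathway, then
#' computes and standardizes the pathway-specific score. A variant
#' mapped to genes in several pathways contributes to each of their
#' scores. Pathways with zero assigned SNPs are skipped with a warning.
#'
#' @param w harmonized [weight_set()] (the parent PRS).
#' @param map a `snp_gene_map` built from `w`'s non-zero entries.
#' @param enriched character vector of pathway names to partition by.
#' @param pathways named list of gene sets.
#' @param g a [genotype_matrix()].
#' @param missing_policy passed to [compute_prs()].
#' @return named list of standardized `score_vector`s, one per pathway
#'   with >= 1 assigned SNP; each carries attribute `n_snps_used`.
#' @export
build_partitioned_scores <- function(w, map, enriched, pathways, g,
                                     missing_policy = "mean_impute") {
  stopifnot(length(enriched) >= 1)
  nz <- w$entries$variant_id[w$entries$weight != 0]
  mp <- map$map[map$map$variant_id %in% nz, , drop = FALSE]
  out <- list()
  for (nm in enriched) {
    genes_in <- pathways[[nm]]
    vids <- unique(mp$variant_id[mp$gene_id %in% genes_in])
    if (length(vids) == 0) {
      warning("pathway '", nm, "' has zero assigned SNPs; skipped")
      next
    }
    wp <- restrict_weights(w, vids)
    wp$prs_name <- paste0(w$prs_name, "|", nm)
    out[[nm]] <- standardize(compute_prs(g, wp, missing_policy))
  }
  out
}

#' Association scan of partitioned scores
#'
#' Runs the full phenome-wide scan on each pathway-specific score with
#' the same covariates and per-score BH families as the parent scan —
#' every phenotype is tested regardless of whether the parent PRS
#' association was significant.
#'
#' @param partitioned named list from [build_partitioned_scores()].
#' @param pt a [phenotype_table()].
#' @param ... passed to [run_phewas()].
#' @return an `assoc_table`.
#' @export
run_partitioned_phewas <- function(partitioned, pt, ...) {
  run_phewas(unname(partitioned), pt, ...)
}

#' Write an enrichment table or SNP-gene map to TSV
#' @param x enrichment data.frame or `snp_gene_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pathway_table <- function(x, path) {
  tab <- if (inherits(x, "snp_gene_map")) x$map else as.data.frame(x)
  data.table::fwrite(tab, path, sep = "\t", quote = FALSE)
  invisible(path)
}
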