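# Readers/writers for external formats, variant QC and weight harmonization.

#' Read genotype dosages from VCF or the TSV dosage dialect
#'
#' VCF input uses the per-genotype `DS` field when present, otherwise hard
#' genotypes from `GT` (0/1/2 counted alleles). The counted allele (`a1`)
#' is the ALT allele. Multi-allelic records are rejected: downstream logic
#' assumes unique bi-allelic SNPs.
#'
#' The TSV dialect is a plain-text sample-by-variant table: a `sample_id`
#' column, then one column per variant named by variant id, dosages as
#' numbers with `NA` for missing. Variant metadata travel in a companion
#' file `<path>.variants` (columns variant_id, chrom, pos, a1, a2,
#' info_r2) written by [write_genotypes_tsv()].
#'
#' @param path input file.
#' @param format `"vcf"` or `"tsv"`.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("vcf", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_tsv(path)
}

read_genotypes_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  alt <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt)
  if (any(n_alt != 1)) {
    bad <- which(n_alt != 1)[1]
    stop("multi-allelic record not supported (variant ",
         rownames(vcf)[bad], "); split or drop it first")
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(VariantAnnotation::ref(vcf))
  altc <- as.character(unlist(alt))
  ids <- rownames(vcf)
  if (anyDuplicated(ids))
    stop("duplicate variant id in VCF: ", ids[duplicated(ids)][1])
  gen <- VariantAnnotation::geno(vcf)
  # a header may declare DS without any record carrying it: fall back
  has_ds <- "DS" %in% names(gen) && !all(is.na(gen$DS))
  if (has_ds) {
    ds <- gen$DS                       # variants x samples
    mode(ds) <- "numeric"
  } else if ("GT" %in% names(gen)) {
    gt <- gen$GT
    ds <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    clean <- gsub("\\|", "/", gt)
    ds[clean == "0/0"] <- 0
    ds[clean %in% c("0/1", "1/0")] <- 1
    ds[clean == "1/1"] <- 2
    unknown <- !(clean %in% c("0/0", "0/1", "1/0", "1/1", "./.", ".")) &
      !is.na(clean)
    if (any(unknown))
      stop("unparseable GT value '", gt[unknown][1], "'")
  } else {
    stop("VCF has neither DS nor GT genotype fields")
  }
  info <- VariantAnnotation::info(vcf)
  info_r2 <- rep(NA_real_, length(ids))
  for (f in c("R2", "INFO", "DR2")) {
    if (f %in% names(info)) { info_r2 <- as.numeric(info[[f]]); break }
  }
  variants <- data.frame(
    variant_id = ids,
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    a1 = altc, a2 = ref,
    info_r2 = info_r2,
    stringsAsFactors = FALSE)
  genotype_matrix(t(ds), variants)
}

read_genotypes_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          na.strings = "NA", data.table = FALSE)
  if (names(dt)[1] != "sample_id")
    stop("TSV dosage dialect must start with a sample_id column (",
         path, ")")
  ids <- as.character(dt$sample_id)
  m <- as.matrix(dt[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric dosage value in ", path)
  storage.mode(m) <- "double"
  rownames(m) <- ids
  vpath <- paste0(path, ".variants")
  if (file.exists(vpath)) {
    variants <- data.table::fread(vpath, sep = "\t", header = TRUE,
                                  data.table = FALSE,
                                  colClasses = list(character = c(
                                    "variant_id", "chrom", "a1", "a2")))
  } else {
    # metadata-free fallback: ids only, placeholder alleles
    variants <- data.frame(variant_id = colnames(m), chrom = NA_character_,
                           pos = seq_len(ncol(m)), a1 = "A", a2 = "C",
                           info_r2 = NA_real_, stringsAsFactors = FALSE)
  }
  if (!identical(variants$variant_id, colnames(m)))
    stop("variant metadata order does not match dosage columns in ", path)
  genotype_matrix(m, variants)
}

#' Write a genotype matrix in the TSV dosage dialect
#'
#' Emits `<path>` (sample_id + one dosage column per variant, `NA` for
#' missing) and `<path>.variants` (variant metadata). Numbers are written
#' with full precision (`format = "%.17g"`) so read/write round-trips are
#' bit exact.
#'
#' @param g a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_tsv <- function(g, path) {
  m <- g$dosages
  txt <- apply(m, 2, function(col)
    ifelse(is.na(col), "NA", sprintf("%.17g", col)))
  if (is.null(dim(txt))) txt <- matrix(txt, nrow = nrow(m))
  dt <- data.frame(sample_id = rownames(m), txt, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(dt) <- c("sample_id", colnames(m))
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE, na = "NA")
  data.table::fwrite(g$variants, paste0(path, ".variants"), sep = "\t",
                     quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a SNP weight file
#'
#' Tab-separated with header columns `variant_id`, `chrom`, `pos`,
#' `effect_allele`, `other_allele`, `weight`.
#'
#' @param path weight file.
#' @param prs_name name for the score; defaults to the file stem.
#' @return a [weight_set()].
#' @export
read_weights <- function(path, prs_name = NULL) {
  if (is.null(prs_name))
    prs_name <- sub("\\.[^.]*$", "", basename(path))
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE,
                          colClasses = list(character = c(
                            "variant_id", "chrom", "effect_allele",
                            "other_allele")))
  weight_set(prs_name, dt)
}

#' Write a weight set to TSV
#' @param w a [weight_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_weights <- function(w, path) {
  data.table::fwrite(w$entries, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test conditional on the allele counts. With `n`
#' diploids and `n_a` copies of the minor allele, the conditional
#' probability of observing `h` heterozygotes is proportional to
#' `n! 2^h / (n_AA! n_Aa! n_aa!)`; the p-value sums the probabilities of
#' every heterozygote count of matching parity whose probability does not
#' exceed that of the observed table.
#'
#' @param n_hom_major,n_het,n_hom_minor genotype counts.
#' @return exact two-sided p-value in `(0, 1]`.
#' @examples
#' hwe_exact_test(50, 0, 0)   # monomorphic: 1
#' hwe_exact_test(30, 20, 10)
#' @export
hwe_exact_test <- function(n_hom_major, n_het, n_hom_minor) {
  counts <- c(n_hom_major, n_het, n_hom_minor)
  if (any(counts < 0)) stop("genotype counts must be non-negative")
  if (any(counts != round(counts))) stop("genotype counts must be integers")
  n <- sum(counts)
  if (n < 1) stop("at least one genotype required")
  n_a <- n_het + 2L * min(n_hom_major, n_hom_minor)  # folded minor count
  n_minor <- min(n_a, 2L * n - n_a)
  hets <- seq(n_minor %% 2L, n_minor, by = 2L)
  if (length(hets) == 0L) return(1)
  # log conditional probability up to a shared constant
  logp <- hets * log(2) - lfactorial((n_minor - hets) / 2) -
    lfactorial(hets) - lfactorial(n - (n_minor + hets) / 2)
  logp <- logp - max(logp)
  pr <- exp(logp); pr <- pr / sum(pr)
  obs <- pr[match(n_het, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

#' Variant quality-control filter
#'
#' Retains variants passing all of: folded MAF strictly above
#' `min_maf` (MAF = folded mean dosage / 2 over non-missing samples),
#' missing rate strictly below `max_missing`, exact HWE p strictly above
#' `min_hwe_p` (computed on hard calls obtained by rounding dosages to
#' the nearest integer), and imputation `info_r2` strictly above
#' `min_info_r2` where an info score is present.
#'
#' @param g a [genotype_matrix()].
#' @param thresholds a [qc_thresholds()].
#' @return list with `genotypes` (filtered matrix) and `report`
#'   (per-variant data.frame of metrics, pass flag and failed rules).
#' @export
qc_filter <- function(g, thresholds = qc_thresholds()) {
  stopifnot(inherits(g, "genotype_matrix"),
            inherits(thresholds, "qc_thresholds"))
  d <- g$dosages
  if (ncol(d) == 0) stop("empty genotype matrix")
  n <- nrow(d)
  n_miss <- colSums(is.na(d))
  miss_rate <- n_miss / n
  mean_d <- colMeans(d, na.rm = TRUE)
  maf <- pmin(mean_d / 2, 1 - mean_d / 2)
  hwe_p <- vapply(seq_len(ncol(d)), function(j) {
    hard <- round(d[, j])
    hard <- hard[!is.na(hard)]
    if (length(hard) == 0) return(NA_real_)
    hwe_exact_test(sum(hard == 0), sum(hard == 1), sum(hard == 2))
  }, numeric(1))
  info <- g$variants$info_r2

  fail_maf <- !(maf > thresholds$min_maf)
  fail_miss <- !(miss_rate < thresholds$max_missing)
  fail_hwe <- !is.na(hwe_p) & !(hwe_p > thresholds$min_hwe_p)
  fail_info <- !is.na(info) & !(info > thresholds$min_info_r2)
  fail_allmiss <- is.na(hwe_p)
  pass <- !(fail_maf | fail_miss | fail_hwe | fail_info | fail_allmiss)

  failed_rules <- vapply(seq_along(pass), function(j) {
    r <- c("maf"[fail_maf[j]], "missing"[fail_miss[j]],
           "hwe"[fail_hwe[j]], "info_r2"[fail_info[j]],
           "all_missing"[fail_allmiss[j]])
    paste(r, collapse = ";")
  }, character(1))

  report <- data.frame(
    variant_id = g$variants$variant_id,
    maf = maf, missing_rate = miss_rate, hwe_p = hwe_p,
    info_r2 = info, pass = pass, failed_rules = failed_rules,
    stringsAsFactors = FALSE)
  if (!any(pass)) stop("empty after QC: no variant passed the filters")
  out <- genotype_matrix(d[, pass, drop = FALSE],
                         g$variants[pass, , drop = FALSE])
  list(genotypes = out, report = report)
}

STRAND_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

is_ambiguous_pair <- function(a1, a2) {
  ok <- a1 %in% names(STRAND_COMPLEMENT) & a2 %in% names(STRAND_COMPLEMENT)
  ok & unname(STRAND_COMPLEMENT[a1]) == a2
}

#' Harmonize a weight set to a genotype matrix's allele encoding
#'
#' Matches weight entries to genotype variants by `(chrom, pos)` and
#' reconciles alleles: if the weight file's effect allele equals the
#' genotype's counted allele `a1` the weight is kept; if it equals `a2`
#' the weight is negated (the score then counts `a1`); if the alleles
#' match only after strand complementation and `allow_strand_flip` is
#' TRUE, the same logic applies to the complemented alleles.
#' Strand-ambiguous A/T and C/G variants are dropped when
#' `drop_ambiguous` (the default: without allele-frequency comparison
#' their strand cannot be resolved). Entries that cannot be matched are
#' dropped and reported.
#'
#' @param w a [weight_set()].
#' @param variants variant metadata data.frame (e.g. `g$variants`).
#' @param drop_ambiguous drop A/T and C/G pairs (default TRUE).
#' @param allow_strand_flip attempt strand complement matching
#'   (default TRUE). Indels (alleles outside A/C/G/T) never strand-flip.
#' @return a [weight_set()] whose entries are expressed on the genotype
#'   allele encoding, with attribute `"log"` (data.frame of dropped
#'   entries and reasons).
#' @export
harmonize_weights <- function(w, variants, drop_ambiguous = TRUE,
                              allow_strand_flip = TRUE) {
  stopifnot(inherits(w, "weight_set"))
  e <- w$entries
  key_g <- paste(variants$chrom, variants$pos)
  key_w <- paste(e$chrom, e$pos)
  idx <- match(key_w, key_g)

  out <- vector("list", nrow(e))
  drop_reason <- character(nrow(e))
  for (i in seq_len(nrow(e))) {
    j <- idx[i]
    if (is.na(j)) { drop_reason[i] <- "no_position_match"; next }
    ea <- toupper(e$effect_allele[i]); oa <- toupper(e$other_allele[i])
    a1 <- toupper(variants$a1[j]); a2 <- toupper(variants$a2[j])
    snv <- all(c(ea, oa, a1, a2) %in% names(STRAND_COMPLEMENT))
    if (drop_ambiguous && snv && is_ambiguous_pair(ea, oa)) {
      drop_reason[i] <- "strand_ambiguous"; next
    }
    wgt <- NA_real_
    if (ea == a1 && oa == a2) {
      wgt <- e$weight[i]
    } else if (ea == a2 && oa == a1) {
      wgt <- -e$weight[i]
    } else if (allow_strand_flip && snv) {
      ec <- unname(STRAND_COMPLEMENT[ea]); oc <- unname(STRAND_COMPLEMENT[oa])
      if (ec == a1 && oc == a2) wgt <- e$weight[i]
      else if (ec == a2 && oc == a1) wgt <- -e$weight[i]
    }
    if (is.na(wgt)) { drop_reason[i] <- "allele_mismatch"; next }
    out[[i]] <- data.frame(
      variant_id = variants$variant_id[j], chrom = variants$chrom[j],
      pos = variants$pos[j], effect_allele = a1, other_allele = a2,
      weight = wgt, stringsAsFactors = FALSE)
  }
  kept <- !vapply(out, is.null, logical(1))
  if (!any(kept))
    stop("harmonization matched zero variants between '", w$prs_name,
         "' and the genotype data")
  res <- weight_set(w$prs_name, do.call(rbind, out[kept]))
  attr(res, "log") <- data.frame(
    variant_id = e$variant_id[!kept],
    reason = drop_reason[!kept], stringsAsFactors = FALSE)
  res
}

#' Read gene models from GFF3 or BED
#'
#' Returns unified 1-based inclusive gene intervals. GFF3 rows of type
#' `gene` are used (all rows if none are typed `gene`); gene ids come
#' from the `ID`/`gene_id`/`Name` attribute. BED (0-based half-open) is
#' converted on read; column 4 supplies the gene id.
#'
#' @param path annotation file.
#' @param format `"gff3"` or `"bed"`; guessed from the extension when
#'   omitted.
#' @return data.frame with `gene_id`, `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @export
read_gene_models <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("gff", "gff3")) "gff3"
              else if (ext == "bed") "bed"
              else stop("cannot guess format from extension '", ext, "'")
  }
  format <- match.arg(format, c("gff3", "bed"))
  gr <- if (format == "gff3") rtracklayer::import(path, format = "gff3")
        else rtracklayer::import(path, format = "bed")
  md <- S4Vectors::mcols(gr)
  if (format == "gff3" && "type" %in% names(md) &&
      any(md$type == "gene")) gr <- gr[md$type == "gene"]
  md <- S4Vectors::mcols(gr)
  id <- NULL
  for (f in c("ID", "gene_id", "Name", "name")) {
    if (f %in% names(md) && !all(is.na(md[[f]]))) {
      id <- as.character(md[[f]]); break
    }
  }
  if (is.null(id)) id <- paste0("gene", seq_along(gr))
  out <- data.frame(
    gene_id = id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),   # rtracklayer converts BED to 1-based
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE)
  if (any(out$end < out$start))
    stop("gene interval with end < start: ", out$gene_id[out$end < out$start][1])
  out
}

#' Read a GMT pathway database
#'
#' One named gene set per tab-separated line: set id, description, then
#' member genes. Duplicate genes within a set are collapsed; sets that
#' are empty after de-duplication are retained (size 0) and flagged with
#' a warning.
#'
#' @param path GMT file.
#' @return named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 2) stop("malformed GMT line: ", substr(l, 1, 60))
    unique(f[-(1:2)][nzchar(f[-(1:2)])])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  empty <- lengths(sets) == 0
  if (any(empty))
    warning("empty pathway set(s) after de-duplication: ",
            paste(names(sets)[empty], collapse = ", "))
  sets
}

#' Write gene models as GFF3
#' @param genes data.frame as returned by [read_gene_models()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\tprsphewas\tgene\t%d\t%d\t.\t+\t.\tID=%s",
                     genes$chrom, genes$start, genes$end, genes$gene_id))
  writeLines(lines, path)
  invisible(path)
}

#' Write a pathway database as GMT
#' @param sets named list of gene-id vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}
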