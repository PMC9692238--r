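## Readers, per-sample SNP filters, gene-level aggregation and gene filters
## for the ASE and total-expression analyses.

.snp_required_cols <- c("contig", "position", "refAllele", "altAllele",
                        "refCount", "altCount")

#' Read ASEReadCounter-style SNP allelic count tables
#'
#' Reads one or more per-sample TSV files with columns contig, position
#' (1-based), refAllele, altAllele, refCount, altCount (variantID and
#' totalCount optional). The reference allele is the maternal/tester (B73)
#' allele under the common-tester crossing design; the alternate allele is
#' the landrace allele.
#'
#' Rows where `refCount + altCount != totalCount` are reported with their
#' line numbers and the totals are recomputed from the allele counts.
#'
#' @param paths character vector of file paths.
#' @param sample_ids sample identifier per path; defaults to the file name
#'   without extension.
#' @return a `data.table` with a `sample_id` column prepended.
#' @export
read_snp_counts <- function(paths, sample_ids = NULL) {
  if (is.null(sample_ids))
    sample_ids <- sub("\\.[^.]*$", "", basename(paths))
  stopifnot(length(sample_ids) == length(paths))
  out <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    tab <- data.table::fread(paths[i], sep = "\t", header = TRUE)
    miss <- setdiff(.snp_required_cols, names(tab))
    if (length(miss))
      stop("SNP count file '", paths[i], "' is missing required column(s): ",
           paste(miss, collapse = ", "))
    if (nrow(tab) > 0) {
      if (any(tab$refCount < 0 | tab$altCount < 0))
        stop("SNP count file '", paths[i], "' contains negative counts")
      if (any(tab$position < 1))
        stop("SNP count file '", paths[i], "' contains positions < 1")
      recomputed <- tab$refCount + tab$altCount
      if ("totalCount" %in% names(tab)) {
        bad <- which(tab$totalCount != recomputed)
        if (length(bad))
          warning("file '", paths[i], "': refCount+altCount != totalCount on ",
                  length(bad), " row(s) (lines ",
                  paste(utils::head(bad + 1L, 5), collapse = ", "),
                  if (length(bad) > 5) ", ..." else "",
                  "); totals recomputed from allele counts")
      }
      tab$totalCount <- recomputed
    } else if (!"totalCount" %in% names(tab)) {
      tab$totalCount <- integer()
    }
    tab <- cbind(data.table::data.table(sample_id = rep(sample_ids[i],
                                                        nrow(tab))), tab)
    out[[i]] <- tab
  }
  data.table::rbindlist(out, fill = TRUE)
}

#' Read a gene x sample count matrix from TSV
#'
#' First column is the gene id; remaining columns are samples.
#' @param path TSV path.
#' @return integer matrix with gene rownames.
#' @export
read_count_matrix <- function(path) {
  tab <- data.table::fread(path, sep = "\t", header = TRUE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  storage.mode(m) <- "integer"
  m
}

#' Read a sample metadata table from TSV
#' @param path TSV path.
#' @return a `data.table`, one row per sample; `sample_id` must be unique.
#' @export
read_metadata <- function(path) {
  tab <- data.table::fread(path, sep = "\t", header = TRUE)
  if (anyDuplicated(tab$sample_id))
    stop("metadata has duplicated sample_id values")
  tab
}

#' Read exon intervals per gene from GFF3 or BED
#'
#' GFF3 coordinates are 1-based inclusive; BED is 0-based half-open
#' (`rtracklayer` converts both to 1-based closed `GRanges`). From GFF3,
#' `exon` features are used (falling back to `gene` features when no exons
#' are annotated) and the gene id is taken from the `gene_id` attribute,
#' else from `Parent`, else from `ID`. From BED, the `name` column is the
#' gene id.
#'
#' @param path annotation file (.gff/.gff3 or .bed).
#' @return a `GRanges` of exon intervals with a `gene_id` metadata column.
#' @export
read_gene_annotation <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  if (ext %in% c("gff", "gff3")) {
    gr <- rtracklayer::import(path, format = "gff3")
    sel <- if (any(gr$type == "exon")) gr[gr$type == "exon"] else
      gr[gr$type == "gene"]
    gid <- if (!is.null(sel$gene_id)) as.character(sel$gene_id)
    else if (!is.null(sel$Parent) && all(lengths(sel$Parent) > 0))
      vapply(sel$Parent, function(x) as.character(x)[1], "")
    else as.character(sel$ID)
    S4Vectors::mcols(sel) <- S4Vectors::DataFrame(gene_id = gid)
  } else if (ext == "bed") {
    sel <- rtracklayer::import(path, format = "bed")
    S4Vectors::mcols(sel) <- S4Vectors::DataFrame(gene_id = as.character(sel$name))
  } else stop("unsupported annotation format: .", ext)
  if (length(sel) == 0)
    stop("annotation '", path, "' contains zero exon intervals")
  sel
}

#' Assign SNPs to genes by exon overlap
#'
#' Each SNP (1-based position) is assigned to the gene whose exon contains
#' it, with inclusive interval ends. SNPs contained in no exon are dropped;
#' SNPs contained in exons of more than one gene are ambiguous and also
#' dropped. The drop tallies are attached as attribute `"assignment_report"`.
#'
#' @param snps a SNP `data.table` (from [read_snp_counts()]) with `contig`
#'   and `position` columns.
#' @param annotation a `GRanges` of exons with `gene_id` (from
#'   [read_gene_annotation()]).
#' @return the SNP table with a `gene_id` column, ambiguous/unassigned rows
#'   removed.
#' @export
assign_snps_to_genes <- function(snps, annotation) {
  if (length(annotation) == 0)
    stop("annotation contains zero exon intervals")
  if (nrow(snps) == 0) {
    out <- data.table::copy(snps); out$gene_id <- character()
    attr(out, "assignment_report") <-
      list(assigned = 0L, outside = 0L, ambiguous = 0L)
    return(out)
  }
  gr <- GenomicRanges::GRanges(snps$contig,
                               IRanges::IRanges(snps$position, width = 1L))
  hits <- GenomicRanges::findOverlaps(gr, annotation, ignore.strand = TRUE)
  gid <- annotation$gene_id[S4Vectors::subjectHits(hits)]
  qh <- S4Vectors::queryHits(hits)
  ## unique gene per SNP row (a SNP in several exons of one gene is fine)
  per_snp <- split(gid, qh)
  n_genes_hit <- vapply(per_snp, function(g) length(unique(g)), 0L)
  hit_rows <- as.integer(names(per_snp))
  uniq_rows <- hit_rows[n_genes_hit == 1L]
  ambiguous <- sum(n_genes_hit > 1L)
  assigned_gene <- vapply(per_snp[n_genes_hit == 1L], `[`, "", 1L)
  out <- snps[uniq_rows, ]
  out$gene_id <- assigned_gene
  attr(out, "assignment_report") <- list(
    assigned = length(uniq_rows),
    outside = nrow(snps) - length(hit_rows),
    ambiguous = as.integer(ambiguous))
  out
}

#' Per-sample SNP filters that avoid biasing ASE ratios
#'
#' Keeps a SNP in a sample iff (i) both alleles were detected
#' (`refCount >= 1` and `altCount >= 1`), (ii) total coverage
#' `refCount + altCount >= min_total`, and (iii) the SNP-level ratio
#' satisfies `|log2(altCount) - log2(refCount)| < log2_cap`.
#'
#' Filter (i) removes apparently homozygous calls: under the common-tester
#' design every locus carries a tester allele, so keeping landrace-only
#' sites while dismissing tester-only sites as homozygous would bias gene
#' ASE toward the landrace allele. Filter (iii) removes extreme SNP ratios
#' that are typically sequencing-error artifacts at high coverage, which
#' would otherwise bias ratios toward the reference allele.
#'
#' The attached `"filter_report"` tallies, for each rule, the rows it drops
#' exclusively (failing only that rule) and cumulatively (failing it at all).
#'
#' @param snps SNP count table with `refCount`, `altCount`.
#' @param min_total minimum total reads covering the SNP (default 10).
#' @param log2_cap strict bound on the absolute SNP log2 ratio (default 2).
#' @return the filtered table, with attribute `"filter_report"`.
#' @export
filter_ase_snps <- function(snps, min_total = 10, log2_cap = 2) {
  ref <- snps$refCount; alt <- snps$altCount
  fail_bial <- !(ref >= 1 & alt >= 1)
  fail_total <- (ref + alt) < min_total
  ratio <- log2(alt) - log2(ref)           # +/-Inf at monoallelic sites
  fail_ratio <- !(abs(ratio) < log2_cap)   # strict: |ratio| >= cap drops
  fail_ratio[fail_bial] <- TRUE            # undefined ratio counts as fail
  keep <- !(fail_bial | fail_total | fail_ratio)
  n_fail <- fail_bial + fail_total + fail_ratio
  report <- data.table::data.table(
    rule = c("both_alleles_detected", "min_total_reads", "log2_ratio_cap"),
    cumulative_drops = c(sum(fail_bial), sum(fail_total), sum(fail_ratio)),
    exclusive_drops = c(sum(fail_bial & n_fail == 1L),
                        sum(fail_total & n_fail == 1L),
                        sum(fail_ratio & n_fail == 1L))
  )
  out <- snps[keep, ]
  attr(out, "filter_report") <- report
  out
}

#' Construct a gene-level allelic count container
#'
#' @param landrace,b73 genes x samples count matrices with identical
#'   dimnames.
#' @return list of class `"gene_allelic_matrix"` with elements `landrace`,
#'   `b73`, `total` (ASE-informative reads, landrace + B73) and `log2ase`
#'   (`log2(landrace) - log2(b73)`, `NA` where either allele count is zero).
#' @export
gene_allelic_matrix <- function(landrace, b73) {
  stopifnot(identical(dim(landrace), dim(b73)),
            identical(dimnames(landrace), dimnames(b73)))
  log2ase <- log2(landrace) - log2(b73)
  log2ase[landrace == 0 | b73 == 0] <- NA_real_
  structure(list(landrace = landrace, b73 = b73,
                 total = landrace + b73, log2ase = log2ase),
            class = "gene_allelic_matrix")
}

#' @export
print.gene_allelic_matrix <- function(x, ...) {
  cat("gene_allelic_matrix:", nrow(x$landrace), "genes x",
      ncol(x$landrace), "samples; ",
      round(100 * mean(is.na(x$log2ase)), 1), "% log2ASE missing\n")
  invisible(x)
}

#' Aggregate allelic counts to gene level
#'
#' `mode = "read_assignment"` counts each read once per gene per allele from
#' a read-assignment table (columns `sample_id`, `read_id`, `gene_id`,
#' `allele` in `{"landrace","B73"}`); rows are de-duplicated so a read
#' overlapping several SNPs of one gene contributes once. This mirrors
#' counting reads from allele-split alignments and is the default when a
#' read table exists.
#'
#' `mode = "snp_sum"` sums SNP-level allelic counts within each gene
#' (landrace = altCount, B73 = refCount). This is an approximation: a read
#' spanning k SNPs of a gene is counted k times, so gene totals are inflated
#' when reads span multiple SNPs, although the ASE ratio is much less
#' affected.
#'
#' @param x filtered SNP table with `gene_id` (snp_sum) or read-assignment
#'   table (read_assignment).
#' @param mode counting mode.
#' @param samples optional sample ordering for the output columns.
#' @return a [gene_allelic_matrix()].
#' @export
aggregate_gene_allelic_counts <- function(x,
                                          mode = c("read_assignment", "snp_sum"),
                                          samples = NULL) {
  mode <- match.arg(mode)
  if (mode == "snp_sum") {
    need <- c("sample_id", "gene_id", "refCount", "altCount")
    if (!all(need %in% names(x))) stop("snp_sum mode needs columns: ",
                                       paste(need, collapse = ", "))
    agg <- x[, list(landrace = sum(altCount), b73 = sum(refCount)),
             by = c("gene_id", "sample_id")]
  } else {
    need <- c("sample_id", "read_id", "gene_id", "allele")
    if (!all(need %in% names(x))) stop("read_assignment mode needs columns: ",
                                       paste(need, collapse = ", "))
    u <- unique(x[, need, with = FALSE])
    agg <- u[, list(n = .N), by = c("gene_id", "sample_id", "allele")]
    agg <- data.table::dcast(agg, gene_id + sample_id ~ allele,
                             value.var = "n", fill = 0L)
    if (!"landrace" %in% names(agg)) agg$landrace <- 0L
    if (!"B73" %in% names(agg)) agg$B73 <- 0L
    data.table::setnames(agg, "B73", "b73")
  }
  genes <- sort(unique(agg$gene_id))
  if (is.null(samples)) samples <- sort(unique(agg$sample_id))
  L <- matrix(0L, length(genes), length(samples),
              dimnames = list(genes, samples))
  B <- L
  gi <- match(agg$gene_id, genes); si <- match(agg$sample_id, samples)
  keep <- !is.na(si)
  L[cbind(gi[keep], si[keep])] <- as.integer(agg$landrace[keep])
  B[cbind(gi[keep], si[keep])] <- as.integer(agg$b73[keep])
  gene_allelic_matrix(L, B)
}

.group_factor <- function(metadata, samples) {
  idx <- match(samples, metadata$sample_id)
  if (anyNA(idx)) stop("metadata is missing ",
                       sum(is.na(idx)), " sample(s)")
  grp <- interaction(metadata$population[idx], metadata$elevation[idx],
                     drop = FALSE)
  if (any(table(grp) == 0))
    stop("population-by-elevation group(s) with zero samples: ",
         paste(names(which(table(grp) == 0)), collapse = ", "))
  grp
}

#' Gene inclusion filter for the ASE analysis
#'
#' Keeps a gene iff, in *each* of the population-by-elevation groups, at
#' least `min_samples` samples have at least `min_reads` ASE-informative
#' reads (landrace + B73) for that gene. This is deliberately stronger than
#' the total-expression filter: genes with few allelic reads are
#' uninformative for ASE even when informative for expression.
#'
#' @param gam a [gene_allelic_matrix()].
#' @param metadata sample metadata with `sample_id`, `population`,
#'   `elevation`.
#' @param min_samples,min_reads thresholds (defaults 10 and 32).
#' @return the filtered `gene_allelic_matrix`.
#' @export
filter_genes_for_ase <- function(gam, metadata, min_samples = 10,
                                 min_reads = 32) {
  grp <- .group_factor(metadata, colnames(gam$total))
  qual <- gam$total >= min_reads
  per_group <- vapply(levels(grp), function(g)
    rowSums(qual[, grp == g, drop = FALSE]), numeric(nrow(qual)))
  keep <- rowSums(per_group >= min_samples) == nlevels(grp)
  gene_allelic_matrix(gam$landrace[keep, , drop = FALSE],
                      gam$b73[keep, , drop = FALSE])
}

#' Gene inclusion filter for the total-expression analysis
#'
#' Keeps a gene iff *at least one* population-by-elevation group has at
#' least `min_samples` samples with at least `min_reads` reads (any-group
#' rule, versus the all-group rule of [filter_genes_for_ase()]).
#'
#' @param counts genes x samples count matrix.
#' @inheritParams filter_genes_for_ase
#' @return the filtered count matrix.
#' @export
filter_genes_for_expression <- function(counts, metadata, min_samples = 10,
                                        min_reads = 32) {
  grp <- .group_factor(metadata, colnames(counts))
  qual <- counts >= min_reads
  per_group <- vapply(levels(grp), function(g)
    rowSums(qual[, grp == g, drop = FALSE]), numeric(nrow(qual)))
  keep <- rowSums(per_group >= min_samples) >= 1
  counts[keep, , drop = FALSE]
}

#' TMM normalization factors
#'
#' Trimmed-mean-of-M-values between-sample normalization (30% trim on
#' M-values, 5% on A-values; reference sample chosen by upper-quartile
#' proximity to the mean), rescaled so the factors have geometric mean 1.
#' Thin wrapper around `edgeR::calcNormFactors`.
#'
#' @param counts genes x samples count matrix with at least 2 samples.
#' @return named numeric vector of factors.
#' @export
tmm_normalization_factors <- function(counts) {
  if (ncol(counts) < 2) stop("TMM needs at least 2 samples")
  zero <- colSums(counts) == 0
  if (any(zero))
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[zero], collapse = ", "))
  f <- edgeR::calcNormFactors(counts, method = "TMM")
  stats::setNames(f, colnames(counts))
}

#' Over-dispersion check for gene-level ASE
#'
#' Compares the observed among-sample variance of log2ASE per gene against a
#' counting-only Monte-Carlo null in which landrace counts are resampled
#' binomially at each sample's observed total and the gene's pooled landrace
#' fraction. Observed variance well above the null indicates biological (or
#' technical) over-dispersion beyond counting variance.
#'
#' @param gam a [gene_allelic_matrix()].
#' @param n_rep Monte-Carlo replicates per gene.
#' @param min_obs minimum non-missing samples per gene.
#' @return `data.table` with per-gene observed and null variance and their
#'   ratio.
#' @export
ase_overdispersion_check <- function(gam, n_rep = 100, min_obs = 5) {
  genes <- rownames(gam$total)
  obs_var <- null_var <- rep(NA_real_, length(genes))
  for (g in seq_along(genes)) {
    ok <- !is.na(gam$log2ase[g, ])
    if (sum(ok) < min_obs) next
    obs_var[g] <- stats::var(gam$log2ase[g, ok])
    tot <- gam$total[g, ok]
    p_hat <- sum(gam$landrace[g, ok]) / sum(tot)
    v <- numeric(n_rep)
    for (r in seq_len(n_rep)) {
      L <- stats::rbinom(length(tot), tot, p_hat)
      lr <- log2(L) - log2(tot - L)
      lr <- lr[is.finite(lr)]
      v[r] <- if (length(lr) >= 2) stats::var(lr) else NA_real_
    }
    null_var[g] <- mean(v, na.rm = TRUE)
  }
  data.table::data.table(gene_id = genes, obs_var = obs_var,
                         null_var = null_var,
                         ratio = obs_var / null_var)
}
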