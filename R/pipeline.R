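## End-to-end orchestration: per-tissue DASE / DE fits, meta-analysis across
## the population-by-tissue conditions, convergence calls, and a
## config-driven runner with deterministic outputs.

#' Sample quality filter on mapped reads
#'
#' Drops samples whose total mapped reads fall below `min_mapped`.
#'
#' @param counts genes x samples count matrix.
#' @param metadata sample metadata (`sample_id`).
#' @param min_mapped minimum total reads (default 2e6).
#' @return list: `counts`, `metadata` (filtered), `dropped` (sample ids).
#' @export
sample_qc <- function(counts, metadata, min_mapped = 2e6) {
  tot <- colSums(counts)
  keep <- tot >= min_mapped
  if (!any(keep)) stop("all samples fall below ", min_mapped, " mapped reads")
  list(counts = counts[, keep, drop = FALSE],
       metadata = metadata[metadata$sample_id %in% colnames(counts)[keep], ],
       dropped = colnames(counts)[!keep])
}

#' Single-tissue differential ASE fit
#'
#' Runs the ASE modeling chain for one site:tissue: design construction,
#' ASE-adapted voom weights, precision-weighted least squares,
#' empirical-Bayes moderation, and extraction of the per-population
#' elevation effects.
#'
#' @param gam a filtered [gene_allelic_matrix()] for the tissue's samples.
#' @param metadata metadata rows for those samples (same order as the
#'   matrix columns).
#' @param cell_scores optional covariate matrix for [build_design()].
#' @return `data.table` of per-gene, per-population `beta`/`se` (moderated),
#'   with the fit attached as attribute `"fit"`.
#' @export
dase_fit_tissue <- function(gam, metadata, cell_scores = NULL) {
  md <- metadata[match(colnames(gam$log2ase), metadata$sample_id), ]
  design <- build_design(md, cell_scores = cell_scores)
  vw <- ase_voom(gam$log2ase, gam$total, design)
  fit <- fit_weighted_lm(gam$log2ase, design, vw$weights)
  fit <- ebayes_moderate(fit)
  eff <- extract_elevation_effects(fit)
  attr(eff, "fit") <- fit
  eff
}

#' Single-tissue differential expression fit
#'
#' Count-mode analogue of [dase_fit_tissue()]: TMM factors, voom log2-CPM
#' and weights, weighted least squares, moderation, effect extraction.
#'
#' @param counts filtered genes x samples count matrix for one tissue.
#' @inheritParams dase_fit_tissue
#' @return as [dase_fit_tissue()]; the log2-CPM matrix is attached as
#'   attribute `"E"`.
#' @export
de_fit_tissue <- function(counts, metadata, cell_scores = NULL) {
  md <- metadata[match(colnames(counts), metadata$sample_id), ]
  design <- build_design(md, cell_scores = cell_scores)
  f <- tmm_normalization_factors(counts)
  v <- voom_counts(counts, f, design)
  fit <- fit_weighted_lm(v$E, design, v$weights)
  fit <- ebayes_moderate(fit)
  eff <- extract_elevation_effects(fit)
  attr(eff, "fit") <- fit
  attr(eff, "E") <- v$E
  eff
}

#' Assemble per-tissue effect tables into condition matrices
#'
#' Binds single-tissue effect tables into genes x conditions `Bhat`/`Shat`
#' matrices with condition columns named `<population>:<tissue>`; genes not
#' assayed in a tissue are `NA`.
#'
#' @param effects named list of effect tables (one per tissue, names =
#'   tissue labels) as returned by [dase_fit_tissue()]/[de_fit_tissue()].
#' @return list: `Bhat`, `Shat`, `conditions` (`data.table` with
#'   `condition`, `population`, `tissue`).
#' @export
collect_effect_matrices <- function(effects) {
  stopifnot(length(names(effects)) == length(effects))
  long <- data.table::rbindlist(lapply(names(effects), function(tt)
    cbind(effects[[tt]][, c("gene_id", "population", "beta", "se")],
          tissue = tt)))
  long$condition <- paste0(long$population, ":", long$tissue)
  genes <- sort(unique(long$gene_id))
  conds <- sort(unique(long$condition))
  Bhat <- Shat <- matrix(NA_real_, length(genes), length(conds),
                         dimnames = list(genes, conds))
  gi <- match(long$gene_id, genes); ci <- match(long$condition, conds)
  Bhat[cbind(gi, ci)] <- long$beta
  Shat[cbind(gi, ci)] <- long$se
  cond_tab <- unique(long[, c("condition", "population", "tissue")])
  data.table::setorder(cond_tab, condition)
  list(Bhat = Bhat, Shat = Shat, conditions = cond_tab)
}

#' Per-population summaries of a meta-analysis result
#'
#' For each population, the overall lfsr is the minimum lfsr over that
#' population's observed conditions and the effect estimate is the mean
#' posterior effect over those conditions (the per-tissue true effects are
#' typically near-perfectly correlated, so the average is a stable single
#' summary).
#'
#' @param res a `"mash_result"`.
#' @param conditions the `conditions` table from
#'   [collect_effect_matrices()].
#' @return `data.table`: `gene_id`, `population`, `lfsr`, `post_mean`.
#' @export
population_summary <- function(res, conditions) {
  out <- lapply(unique(conditions$population), function(p) {
    cols <- conditions$condition[conditions$population == p]
    lf <- res$lfsr[, cols, drop = FALSE]
    pm <- res$post_mean[, cols, drop = FALSE]
    data.table::data.table(
      gene_id = rownames(lf), population = p,
      lfsr = apply(lf, 1, function(x)
        if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE)),
      post_mean = rowMeans(pm, na.rm = TRUE))
  })
  data.table::rbindlist(out)
}

#' Run the differential-ASE pipeline on a simulated cohort
#'
#' The full chain for each site:tissue: per-sample SNP filters, gene-level
#' aggregation of allelic counts, the mapped-read sample filter, the
#' all-group ASE gene filter, and the weighted single-tissue fit; then the
#' multivariate shrinkage meta-analysis across all population-by-tissue
#' conditions, per-population overall lfsr, and the convergence
#' classification between the two populations.
#'
#' @param cohort a `sim_cohort` (or a compatible list with `snp_counts`,
#'   `counts`, `metadata`).
#' @param lfsr_alpha significance threshold on the overall lfsr.
#' @param min_samples,min_reads ASE gene-filter thresholds.
#' @param snp_min_total,snp_log2_cap per-sample SNP filter thresholds.
#' @param min_mapped sample QC threshold on total mapped reads.
#' @return list of class `"dase_result"`: `effects` (per-tissue tables),
#'   `Bhat`, `Shat`, `conditions`, `mash` (`"mash_result"`), `populations`
#'   (per-gene per-population lfsr and effect), `convergence`
#'   (classification table), `overlap` (hypergeometric test inputs and p),
#'   `concordance` (all-gene vs convergent-subset correlations, when
#'   defined).
#' @export
run_dase <- function(cohort, lfsr_alpha = 0.05, min_samples = 10,
                     min_reads = 32, snp_min_total = 10, snp_log2_cap = 2,
                     min_mapped = 2e6) {
  md <- cohort$metadata
  qc <- sample_qc(cohort$counts, md, min_mapped = min_mapped)
  md <- qc$metadata
  snps <- cohort$snp_counts[cohort$snp_counts$sample_id %in% md$sample_id, ]
  snps <- filter_ase_snps(snps, min_total = snp_min_total,
                          log2_cap = snp_log2_cap)
  effects <- list()
  for (tt in sort(unique(md$site_tissue))) {
    md_t <- md[md$site_tissue == tt, ]
    gam <- aggregate_gene_allelic_counts(
      snps[snps$sample_id %in% md_t$sample_id, ], mode = "snp_sum",
      samples = sort(md_t$sample_id))
    gam <- filter_genes_for_ase(gam, md_t, min_samples = min_samples,
                                min_reads = min_reads)
    effects[[tt]] <- dase_fit_tissue(gam, md_t)
  }
  em <- collect_effect_matrices(effects)
  mres <- mash_lite(em$Bhat, em$Shat)
  pops <- population_summary(mres, em$conditions)
  out <- list(effects = effects, Bhat = em$Bhat, Shat = em$Shat,
              conditions = em$conditions, mash = mres, populations = pops)
  pop_names <- unique(pops$population)
  if (length(pop_names) == 2) {
    p1 <- pops[pops$population == pop_names[1], ]
    p2 <- pops[pops$population == pop_names[2], ]
    stopifnot(identical(p1$gene_id, p2$gene_id))
    conv <- classify_convergent(p1$lfsr, p2$lfsr, p1$post_mean, p2$post_mean,
                                alpha = lfsr_alpha, gene_ids = p1$gene_id)
    s <- attr(conv, "summary")
    out$convergence <- conv
    out$overlap <- list(N = nrow(em$Bhat), K = s$K, n = s$n, x = s$overlap,
                        p = if (s$overlap <= min(s$K, s$n) && min(s$K, s$n) > 0)
                          hypergeom_overlap(nrow(em$Bhat), s$K, s$n, s$overlap)
                        else NA_real_)
    if (s$convergent >= 3)
      out$concordance <- effect_concordance(p1$post_mean, p2$post_mean,
                                            which(conv$convergent))
  }
  class(out) <- "dase_result"
  out
}

#' @export
print.dase_result <- function(x, ...) {
  calls <- x$populations[!is.na(x$populations$lfsr) & x$populations$lfsr < 0.05, ]
  cat("dase_result:", nrow(x$Bhat), "genes x", ncol(x$Bhat), "conditions\n")
  for (p in unique(x$populations$population))
    cat("  ", p, ":", sum(calls$population == p), "genes at lfsr < 0.05\n")
  if (!is.null(x$overlap))
    cat("  overlap:", x$overlap$x, "genes, hypergeometric p =",
        format(x$overlap$p, digits = 3), "\n")
  invisible(x)
}

#' Run the differential-expression pipeline on a cohort
#'
#' Count-mode analogue of [run_dase()]: sample QC, the any-group expression
#' filter, TMM + voom + weighted fits per site:tissue, meta-analysis, and
#' convergence classification.
#'
#' @inheritParams run_dase
#' @param cell_scores optional named list of per-tissue covariate matrices.
#' @return list of class `"dase_result"` with the same components.
#' @export
run_de <- function(cohort, lfsr_alpha = 0.05, min_samples = 10,
                   min_reads = 32, min_mapped = 2e6, cell_scores = NULL) {
  md <- cohort$metadata
  qc <- sample_qc(cohort$counts, md, min_mapped = min_mapped)
  md <- qc$metadata
  effects <- list()
  for (tt in sort(unique(md$site_tissue))) {
    md_t <- md[md$site_tissue == tt, ]
    cnt <- qc$counts[, sort(md_t$sample_id), drop = FALSE]
    cnt <- filter_genes_for_expression(cnt, md_t, min_samples = min_samples,
                                       min_reads = min_reads)
    effects[[tt]] <- de_fit_tissue(cnt, md_t,
                                   cell_scores = cell_scores[[tt]])
  }
  em <- collect_effect_matrices(effects)
  mres <- mash_lite(em$Bhat, em$Shat)
  pops <- population_summary(mres, em$conditions)
  out <- list(effects = effects, Bhat = em$Bhat, Shat = em$Shat,
              conditions = em$conditions, mash = mres, populations = pops)
  pop_names <- unique(pops$population)
  if (length(pop_names) == 2) {
    p1 <- pops[pops$population == pop_names[1], ]
    p2 <- pops[pops$population == pop_names[2], ]
    conv <- classify_convergent(p1$lfsr, p2$lfsr, p1$post_mean, p2$post_mean,
                                alpha = lfsr_alpha, gene_ids = p1$gene_id)
    s <- attr(conv, "summary")
    out$convergence <- conv
    out$overlap <- list(N = nrow(em$Bhat), K = s$K, n = s$n, x = s$overlap,
                        p = if (min(s$K, s$n) > 0)
                          hypergeom_overlap(nrow(em$Bhat), s$K, s$n, s$overlap)
                        else NA_real_)
  }
  class(out) <- "dase_result"
  out
}

#' Run IBD classification for all within-family sample pairs
#'
#' For each F1 family, classifies IBD bins between sibling plants (pairs of
#' distinct plants of the same family, using their filtered heterozygous
#' SNP calls for one tissue each) against the genome-wide SNP panel.
#'
#' @param cohort a `sim_cohort`.
#' @param tissue the site:tissue whose samples supply the het calls where
#'   available (one sample per plant is used).
#' @param n_bins bins per chromosome.
#' @param snp_min_total,snp_log2_cap per-sample SNP filter thresholds.
#' @return `data.table` of per-pair bin classifications with `family`,
#'   `plant_a`, `plant_b` columns.
#' @export
run_ibd <- function(cohort, tissue = "MetLeaftip", n_bins = 20,
                    snp_min_total = 10, snp_log2_cap = 2) {
  md <- cohort$metadata
  snps <- filter_ase_snps(cohort$snp_counts, min_total = snp_min_total,
                          log2_cap = snp_log2_cap)
  panel <- unique(cohort$snps[, c("chrom", "pos")])
  data.table::setnames(panel, c("chrom", "pos"), c("contig", "position"))
  ## one representative sample per plant
  md_one <- md[!duplicated(md$plant), ]
  pref <- md[md$site_tissue == tissue, ]
  md_one <- rbind(pref, md_one[!md_one$plant %in% pref$plant, ])
  out <- list()
  for (fam in unique(md_one$family)) {
    pl <- md_one[md_one$family == fam, ]
    if (nrow(pl) < 2) next
    for (i in seq_len(nrow(pl) - 1)) for (j in seq(i + 1, nrow(pl))) {
      het_a <- snps[snps$sample_id == pl$sample_id[i],
                    c("contig", "position")]
      het_b <- snps[snps$sample_id == pl$sample_id[j],
                    c("contig", "position")]
      tab <- ibd_classify_pair(het_a, het_b, panel, n_bins = n_bins)
      tab$family <- fam
      tab$plant_a <- pl$plant[i]; tab$plant_b <- pl$plant[j]
      out[[length(out) + 1]] <- tab
    }
  }
  data.table::rbindlist(out)
}

#' Config-driven pipeline runner
#'
#' Executes the requested stages in dependency order on a simulated cohort
#' and writes per-stage TSV outputs plus a manifest (seed, stage row
#' counts, file checksums). Re-running with the same configuration
#' reproduces byte-identical outputs.
#'
#' @param config list with elements `simulate` (arguments to
#'   [sim_config()]), `stages` (subset of `"simulate"`, `"dase"`, `"de"`,
#'   `"ibd"`), `outdir`, and optional threshold overrides
#'   (`lfsr_alpha`, `min_samples`, `min_reads`, `snp_min_total`,
#'   `snp_log2_cap`, `min_mapped`, `n_bins`).
#' @return the manifest (invisibly written to `manifest.tsv` in `outdir`).
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config), !is.null(config$outdir))
  stages <- config$stages %||% c("simulate", "dase")
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  thr <- function(name, default) config[[name]] %||% default
  manifest <- list()
  note <- function(stage, file, rows) {
    manifest[[length(manifest) + 1]] <<- data.table::data.table(
      stage = stage, file = basename(file), rows = rows,
      md5 = tools::md5sum(file)[[1]])
  }
  cohort <- simulate_cohort(do.call(sim_config, config$simulate %||% list()))
  if ("simulate" %in% stages) {
    fx <- file.path(config$outdir, "fixture")
    write_fixture(cohort, fx)
    note("simulate", file.path(fx, "metadata.tsv"), nrow(cohort$metadata))
  }
  if ("dase" %in% stages) {
    res <- run_dase(cohort,
                    lfsr_alpha = thr("lfsr_alpha", 0.05),
                    min_samples = thr("min_samples", 10),
                    min_reads = thr("min_reads", 32),
                    snp_min_total = thr("snp_min_total", 10),
                    snp_log2_cap = thr("snp_log2_cap", 2),
                    min_mapped = thr("min_mapped", 2e6))
    f <- file.path(config$outdir, "dase_populations.tsv")
    data.table::fwrite(res$populations, f, sep = "\t")
    note("dase", f, nrow(res$populations))
    if (!is.null(res$convergence)) {
      f <- file.path(config$outdir, "dase_convergence.tsv")
      data.table::fwrite(res$convergence, f, sep = "\t")
      note("dase", f, nrow(res$convergence))
    }
  }
  if ("de" %in% stages) {
    res <- run_de(cohort,
                  lfsr_alpha = thr("lfsr_alpha", 0.05),
                  min_samples = thr("min_samples", 10),
                  min_reads = thr("min_reads", 32),
                  min_mapped = thr("min_mapped", 2e6))
    f <- file.path(config$outdir, "de_populations.tsv")
    data.table::fwrite(res$populations, f, sep = "\t")
    note("de", f, nrow(res$populations))
  }
  if ("ibd" %in% stages) {
    res <- run_ibd(cohort, n_bins = thr("n_bins", 20),
                   snp_min_total = thr("snp_min_total", 10),
                   snp_log2_cap = thr("snp_log2_cap", 2))
    f <- file.path(config$outdir, "ibd_bins.tsv")
    data.table::fwrite(res, f, sep = "\t")
    note("ibd", f, nrow(res))
  }
  man <- data.table::rbindlist(manifest)
  man <- cbind(data.table::data.table(seed = cohort$config$seed), man)
  data.table::fwrite(man, file.path(config$outdir, "manifest.tsv"), sep = "\t")
  invisible(man)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
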