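#' Configuration for a synthetic F1 ASE cohort
#'
#' Builds and validates the parameter set for [simulate_cohort()]. The
#' generator emulates a population-level allele-specific expression (ASE)
#' study design: open-pollinated landrace fathers from two populations
#' (highland and lowland classes in each) crossed to a common inbred mother,
#' grown at a highland site (two blocks, leaf tip + leaf base sampled) and a
#' lowland site (one block, leaf tip sampled), giving three site:tissue
#' conditions per family.
#'
#' Defaults follow the emulated study design: 108 F1 families split evenly
#' between two populations and between elevation classes, 10 chromosomes and
#' 3 site:tissues. The per-haplotype cis effect of gene g is
#' \eqn{\theta_{g,h} \sim N(\delta_g \cdot \mathrm{highland}, \tau^2)} in log2
#' units, where \eqn{\delta_g = \delta} for the designated DASE genes and 0
#' otherwise; the expected landrace read fraction is
#' \eqn{p = 2^\theta / (1 + 2^\theta)}. Gene totals are negative binomial
#' around a library-size-scaled mean and the allelic split is beta-binomial
#' with intra-class correlation `bb_rho` (`bb_rho = 0` degenerates to
#' binomial).
#'
#' @param n_families number of F1 families (paternal landrace parents).
#' @param frac_highland fraction of families whose father is a highland
#'   accession (applied within each population).
#' @param populations character vector of population labels.
#' @param n_genes number of genes.
#' @param n_chromosomes number of chromosomes genes are spread over.
#' @param snps_per_gene_mean Poisson mean of exonic SNP count per gene
#'   (truncated at 1).
#' @param n_dase_genes number of genes given a true elevation effect.
#' @param delta highland minus lowland shift of the mean log2 cis effect for
#'   DASE genes (log2 units).
#' @param tau SD of the baseline per-haplotype cis effect (log2 units).
#' @param library_size_mean expected total reads per sample.
#' @param nb_dispersion negative-binomial dispersion of gene totals
#'   (`size = 1/nb_dispersion`).
#' @param bb_rho beta-binomial intra-class correlation of the allelic split,
#'   in `[0, 1)`.
#' @param seq_error_rate per-read probability that the observed allele call
#'   is flipped, creating spurious minor-allele counts at homozygous loci.
#' @param plants_per_family_per_site integer vector `c(Met = 2, PV = 1)`;
#'   the highland-site plants are each sampled for two tissues.
#' @param segments_per_chromosome number of independently segregating
#'   paternal haplotype segments per chromosome (the IBD ground-truth
#'   blocks).
#' @param alt_freq probability that a paternal haplotype carries the
#'   non-reference allele at a given exonic SNP.
#' @param seed integer seed; the whole cohort is a deterministic function of
#'   the configuration including the seed.
#'
#' @return a validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_families = 108,
                       frac_highland = 0.5,
                       populations = c("Mexico", "SouthAmerica"),
                       n_genes = 2000,
                       n_chromosomes = 10,
                       snps_per_gene_mean = 3,
                       n_dase_genes = 200,
                       delta = 1,
                       tau = 0.3,
                       library_size_mean = 5e6,
                       nb_dispersion = 0.1,
                       bb_rho = 0.01,
                       seq_error_rate = 0.001,
                       plants_per_family_per_site = c(Met = 2, PV = 1),
                       segments_per_chromosome = 5,
                       alt_freq = 0.7,
                       seed = 1) {
  cfg <- list(
    n_families = n_families, frac_highland = frac_highland,
    populations = populations, n_genes = n_genes,
    n_chromosomes = n_chromosomes, snps_per_gene_mean = snps_per_gene_mean,
    n_dase_genes = n_dase_genes, delta = delta, tau = tau,
    library_size_mean = library_size_mean, nb_dispersion = nb_dispersion,
    bb_rho = bb_rho, seq_error_rate = seq_error_rate,
    plants_per_family_per_site = plants_per_family_per_site,
    segments_per_chromosome = segments_per_chromosome,
    alt_freq = alt_freq, seed = seed
  )
  chk_count <- function(x, name, min = 1) {
    if (length(x) != 1L || !is.finite(x) || x < min || x != round(x))
      stop("invalid sim_config parameter '", name, "': must be an integer >= ",
           min, call. = FALSE)
  }
  chk_prop <- function(x, name, lo = 0, hi = 1, hi_open = FALSE) {
    bad <- length(x) != 1L || !is.finite(x) || x < lo ||
      (if (hi_open) x >= hi else x > hi)
    if (bad) stop("invalid sim_config parameter '", name, "'", call. = FALSE)
  }
  chk_count(n_families, "n_families"); chk_count(n_genes, "n_genes", min = 0)
  chk_count(n_chromosomes, "n_chromosomes")
  chk_count(n_dase_genes, "n_dase_genes", min = 0)
  chk_count(segments_per_chromosome, "segments_per_chromosome")
  chk_prop(frac_highland, "frac_highland")
  chk_prop(bb_rho, "bb_rho", hi_open = TRUE)
  chk_prop(seq_error_rate, "seq_error_rate")
  chk_prop(alt_freq, "alt_freq")
  if (!is.finite(delta)) stop("invalid sim_config parameter 'delta'", call. = FALSE)
  if (!is.finite(tau) || tau < 0) stop("invalid sim_config parameter 'tau'", call. = FALSE)
  if (!is.finite(snps_per_gene_mean) || snps_per_gene_mean <= 0)
    stop("invalid sim_config parameter 'snps_per_gene_mean'", call. = FALSE)
  if (!is.finite(library_size_mean) || library_size_mean < 1)
    stop("invalid sim_config parameter 'library_size_mean'", call. = FALSE)
  if (!is.finite(nb_dispersion) || nb_dispersion <= 0)
    stop("invalid sim_config parameter 'nb_dispersion'", call. = FALSE)
  if (n_dase_genes > n_genes)
    stop("invalid sim_config parameter 'n_dase_genes': exceeds n_genes", call. = FALSE)
  if (length(populations) < 1L) stop("invalid sim_config parameter 'populations'", call. = FALSE)
  if (!all(c("Met", "PV") %in% names(plants_per_family_per_site)) ||
      any(plants_per_family_per_site < 1))
    stop("invalid sim_config parameter 'plants_per_family_per_site'", call. = FALSE)
  chk_count(seed, "seed", min = -.Machine$integer.max)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_families, "families x", x$n_genes, "genes,",
      x$n_dase_genes, "DASE genes (delta =", x$delta, ", tau =", x$tau, ")\n")
  invisible(x)
}

# multinomial thinning with equal cell probabilities, vectorized over samples:
# splits each element of `total` into `k` parts; returns k x length(total)
.thin_equal <- function(total, k) {
  out <- matrix(0L, nrow = k, ncol = length(total))
  remaining <- as.integer(total)
  for (j in seq_len(k - 1L)) {
    x <- stats::rbinom(length(remaining), remaining, 1 / (k - j + 1L))
    out[j, ] <- x
    remaining <- remaining - x
  }
  out[k, ] <- remaining
  out
}

#' Simulate a synthetic F1 ASE cohort
#'
#' Generates sample metadata, per-sample SNP allelic count tables
#' (ASEReadCounter-style), a gene-by-sample total count matrix, gene
#' annotation, and the full ground truth (cis effects, elevation effects,
#' haplotype inheritance, expected landrace fractions) for a configuration
#' built with [sim_config()].
#'
#' Paternal haplotypes segregate independently within fixed-length
#' chromosome segments, creating identity-by-descent structure between
#' sibling plants of the same family. Each gene's reads are thinned
#' multinomially across its exonic SNPs; at SNPs where the inherited
#' paternal haplotype carries the reference allele (homozygous loci), reads
#' from both alleles report the reference base, so non-reference counts at
#' such loci arise only through `seq_error_rate`.
#'
#' @param config a `sim_config` object.
#' @param emit_reads if `TRUE`, also emit a per-read assignment table
#'   (columns sample_id, read_id, gene_id, allele); intended for small
#'   configurations only.
#' @return a list of class `"sim_cohort"` with elements `metadata`,
#'   `snp_counts` (one `data.table`, long format over samples), `counts`
#'   (genes x samples integer matrix), `genes`, `snps`, `truth`, and
#'   optionally `reads`.
#' @export
simulate_cohort <- function(config, emit_reads = FALSE) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)

  n_pop <- length(config$populations)
  G <- config$n_genes
  chrom_len <- 1e8
  n_seg <- config$segments_per_chromosome
  seg_len <- chrom_len / n_seg

  ## genes, positions, SNPs ---------------------------------------------
  gene_width <- 3000L
  if (G > 0) {
    chrom <- sort(rep_len(seq_len(config$n_chromosomes), G))
    start <- unlist(lapply(split(seq_along(chrom), chrom), function(idx) {
      sort(sample.int(chrom_len - gene_width, length(idx)))
    }), use.names = FALSE)
    genes <- data.table::data.table(
      gene_id = sprintf("gene%05d", seq_len(G)),
      chrom = paste0("chr", chrom),
      start = as.integer(start),
      end = as.integer(start + gene_width - 1L)
    )
    genes$segment <- (chrom - 1L) * n_seg +
      pmin(n_seg, floor((start + gene_width / 2) / seg_len) + 1L)
    n_snps <- pmax(1L, stats::rpois(G, config$snps_per_gene_mean))
    genes$n_snps <- n_snps
    snps <- data.table::data.table(
      gene_id = rep(genes$gene_id, n_snps),
      chrom = rep(genes$chrom, n_snps),
      pos = unlist(lapply(seq_len(G), function(g) {
        sort(sample.int(gene_width, n_snps[g])) + genes$start[g] - 1L
      }), use.names = FALSE)
    )
    bases <- c("A", "C", "G", "T")
    snps$refAllele <- sample(bases, nrow(snps), replace = TRUE)
    snps$altAllele <- vapply(snps$refAllele,
                             function(b) sample(setdiff(bases, b), 1L), "")
    snps$variantID <- paste0(snps$chrom, "_", snps$pos)
  } else {
    genes <- data.table::data.table(gene_id = character(), chrom = character(),
                                    start = integer(), end = integer(),
                                    segment = integer(), n_snps = integer())
    snps <- data.table::data.table(gene_id = character(), chrom = character(),
                                   pos = integer(), refAllele = character(),
                                   altAllele = character(), variantID = character())
  }
  S <- nrow(snps)

  ## families ------------------------------------------------------------
  fam_pop <- rep_len(config$populations, config$n_families)
  n_hi <- round(config$frac_highland * config$n_families)
  elev <- rep("Lowland", config$n_families)
  ## spread highland families evenly over populations
  for (p in config$populations) {
    idx <- which(fam_pop == p)
    k <- round(config$frac_highland * length(idx))
    if (k > 0) elev[idx[seq_len(k)]] <- "Highland"
  }
  lat_range <- stats::setNames(
    rep(list(c(15, 25)), n_pop), config$populations)
  if ("SouthAmerica" %in% config$populations)
    lat_range[["SouthAmerica"]] <- c(-35, -5)
  latitude <- vapply(fam_pop, function(p) stats::runif(1, lat_range[[p]][1],
                                                       lat_range[[p]][2]), 0)
  families <- data.table::data.table(
    family = sprintf("F%03d", seq_len(config$n_families)),
    population = fam_pop, elevation = elev, latitude = round(latitude, 3)
  )

  ## per-haplotype SNP alleles and cis effects --------------------------
  F <- config$n_families
  alt1 <- matrix(stats::runif(S * F) < config$alt_freq, S, F)
  alt2 <- matrix(stats::runif(S * F) < config$alt_freq, S, F)
  dase_genes <- if (config$n_dase_genes > 0 && G > 0)
    sort(sample.int(G, config$n_dase_genes)) else integer()
  delta_g <- numeric(G)
  delta_g[dase_genes] <- config$delta
  hi_shift <- outer(delta_g, as.numeric(families$elevation == "Highland"))
  th1 <- matrix(stats::rnorm(G * F, 0, config$tau), G, F) + hi_shift
  th2 <- matrix(stats::rnorm(G * F, 0, config$tau), G, F) + hi_shift

  ## plants and samples --------------------------------------------------
  n_met <- config$plants_per_family_per_site[["Met"]]
  n_pv <- config$plants_per_family_per_site[["PV"]]
  plants <- data.table::data.table(
    family = rep(families$family, each = n_met + n_pv),
    site = rep(c(rep("Met", n_met), rep("PV", n_pv)), F),
    block = rep(c(seq_len(n_met), seq_len(n_pv)), F)
  )
  plants$plant_id <- paste0(plants$family, "_", plants$site, plants$block)
  n_plants <- nrow(plants)
  n_blocks_total <- config$n_chromosomes * n_seg
  inherit <- matrix(sample(1:2, n_plants * n_blocks_total, replace = TRUE),
                    n_plants, n_blocks_total,
                    dimnames = list(plants$plant_id, NULL))

  tissue_of <- list(Met = c("MetLeaftip", "MetLeafbase"), PV = "PvLeaftip")
  samp_list <- lapply(seq_len(n_plants), function(i) {
    data.table::data.table(plant = plants$plant_id[i],
                           family = plants$family[i],
                           site = plants$site[i], block = plants$block[i],
                           site_tissue = tissue_of[[plants$site[i]]])
  })
  metadata <- data.table::rbindlist(samp_list)
  metadata <- merge(metadata, families, by = "family", sort = FALSE)
  metadata$sample_id <- paste0(metadata$plant, "_", metadata$site_tissue)
  ## sampling team (3 teams, round-robin over randomized field order) per tissue
  metadata$team <- NA_integer_; metadata$field_order <- NA_integer_
  for (tt in unique(metadata$site_tissue)) {
    idx <- which(metadata$site_tissue == tt)
    ord <- sample(length(idx))
    metadata$team[idx] <- ((ord - 1L) %% 3L) + 1L
    metadata$field_order[idx] <- ((ord - 1L) %/% 3L) + 1L
  }
  data.table::setorder(metadata, sample_id)
  n_samp <- nrow(metadata)
  data.table::setcolorder(metadata, c("sample_id", "family", "plant",
                                      "population", "elevation", "latitude",
                                      "block", "team", "field_order",
                                      "site_tissue"))

  ## totals and allelic split -------------------------------------------
  lib <- round(config$library_size_mean * exp(stats::rnorm(n_samp, 0, 0.2)))

  fam_idx <- match(metadata$family, families$family)
  plant_idx <- match(metadata$plant, plants$plant_id)
  hap <- matrix(1L, max(G, 1L), n_samp)  # inherited haplotype per gene x sample
  theta <- matrix(0, max(G, 1L), n_samp)
  if (G > 0) {
    for (s in seq_len(n_samp)) {
      h <- inherit[plant_idx[s], genes$segment]
      hap[, s] <- h
      theta[, s] <- ifelse(h == 1L, th1[, fam_idx[s]], th2[, fam_idx[s]])
    }
  }
  p_mat <- 2^theta / (1 + 2^theta)

  if (G > 0) {
    q <- stats::rlnorm(G, 0, 1); q <- q / sum(q)
    ## the maternal (tester) allele contributes a fixed baseline q/2 per
    ## allele; the paternal cis effect 2^theta scales the landrace allele,
    ## so a cis shift also moves the gene's total expression
    mu <- outer(q / 2, lib) * (1 + 2^theta[seq_len(G), , drop = FALSE])
    totals <- matrix(stats::rnbinom(G * n_samp, mu = mu,
                                    size = 1 / config$nb_dispersion),
                     G, n_samp,
                     dimnames = list(genes$gene_id, metadata$sample_id))
  } else {
    totals <- matrix(integer(), 0, n_samp,
                     dimnames = list(NULL, metadata$sample_id))
  }
  if (G > 0) {
    if (config$bb_rho > 0) {
      a <- p_mat * (1 - config$bb_rho) / config$bb_rho
      b <- (1 - p_mat) * (1 - config$bb_rho) / config$bb_rho
      pp <- matrix(stats::rbeta(G * n_samp, a, b), G, n_samp)
    } else pp <- p_mat
    landrace <- matrix(stats::rbinom(G * n_samp, totals, pp), G, n_samp,
                       dimnames = dimnames(totals))
  } else landrace <- totals
  b73 <- totals - landrace

  ## SNP-level counts by multinomial thinning ---------------------------
  refC <- matrix(0L, S, n_samp); altC <- matrix(0L, S, n_samp)
  if (S > 0) {
    snp_row_of_gene <- split(seq_len(S), snps$gene_id)
    for (g in seq_len(G)) {
      rows <- snp_row_of_gene[[genes$gene_id[g]]]
      k <- length(rows)
      Lp <- .thin_equal(landrace[g, ], k)
      Bp <- .thin_equal(b73[g, ], k)
      het <- matrix(0L, k, n_samp)
      for (s in seq_len(n_samp)) {
        carrier <- if (hap[g, s] == 1L) alt1[rows, fam_idx[s]] else alt2[rows, fam_idx[s]]
        het[, s] <- as.integer(carrier)
      }
      altC[rows, ] <- Lp * het
      refC[rows, ] <- Bp + Lp * (1L - het)
    }
    if (config$seq_error_rate > 0) {
      e <- config$seq_error_rate
      r2a <- matrix(stats::rbinom(S * n_samp, refC, e), S, n_samp)
      a2r <- matrix(stats::rbinom(S * n_samp, altC, e), S, n_samp)
      refC <- refC - r2a + a2r
      altC <- altC - a2r + r2a
    }
  }
  snp_counts <- data.table::data.table(
    sample_id = rep(metadata$sample_id, each = S),
    contig = rep(snps$chrom, n_samp),
    position = rep(snps$pos, n_samp),
    variantID = rep(snps$variantID, n_samp),
    refAllele = rep(snps$refAllele, n_samp),
    altAllele = rep(snps$altAllele, n_samp),
    refCount = as.integer(refC),
    altCount = as.integer(altC),
    gene_id = rep(snps$gene_id, n_samp)
  )
  snp_counts$totalCount <- snp_counts$refCount + snp_counts$altCount
  snp_counts <- snp_counts[snp_counts$totalCount > 0L, ]
  data.table::setorder(snp_counts, sample_id, contig, position)

  truth <- list(
    genes = data.table::data.table(genes,
                                   is_dase = seq_len(max(G, 0)) %in% dase_genes,
                                   delta = delta_g)[seq_len(G), ],
    families = families,
    plants = plants,
    inherit = inherit,
    segments = data.table::data.table(
      chrom = rep(paste0("chr", seq_len(config$n_chromosomes)), each = n_seg),
      segment = seq_len(n_blocks_total),
      start = rep(as.integer((seq_len(n_seg) - 1L) * seg_len + 1), config$n_chromosomes),
      end = rep(as.integer(seq_len(n_seg) * seg_len), config$n_chromosomes)
    ),
    theta_hap1 = th1, theta_hap2 = th2,
    snp_alt_hap1 = alt1, snp_alt_hap2 = alt2,
    expected_p = p_mat[seq_len(G), , drop = FALSE],
    landrace = landrace, b73 = b73,
    dase_gene_ids = genes$gene_id[dase_genes]
  )
  cohort <- list(config = config, metadata = metadata, snp_counts = snp_counts,
                 counts = totals, genes = genes, snps = snps,
                 library_sizes = stats::setNames(lib, metadata$sample_id),
                 truth = truth)
  if (emit_reads) {
    rl <- snp_counts[, c("sample_id", "gene_id", "refCount", "altCount")]
    n_ref <- rl$refCount; n_alt <- rl$altCount
    reads <- data.table::data.table(
      sample_id = c(rep(rl$sample_id, n_ref), rep(rl$sample_id, n_alt)),
      gene_id = c(rep(rl$gene_id, n_ref), rep(rl$gene_id, n_alt)),
      allele = c(rep("B73", sum(n_ref)), rep("landrace", sum(n_alt)))
    )
    reads$read_id <- sprintf("r%07d", seq_len(nrow(reads)))
    cohort$reads <- reads
  }
  class(cohort) <- "sim_cohort"
  cohort
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("sim_cohort:", nrow(x$counts), "genes x", ncol(x$counts), "samples;",
      nrow(x$snp_counts), "SNP count rows;",
      length(x$truth$dase_gene_ids), "true DASE genes\n")
  invisible(x)
}

#' Write a simulated cohort to a plain-text fixture directory
#'
#' Emits per-sample SNP count tables (`snp_counts/<sample>.tsv`, columns
#' contig, position, variantID, refAllele, altAllele, refCount, altCount,
#' totalCount), gene annotation (`genes.gff3`), the total count matrix
#' (`counts.tsv`), sample metadata (`metadata.tsv`) and ground-truth tables
#' (`truth_genes.tsv`, `truth_inherit.tsv`). The files round-trip through
#' [read_snp_counts()], [read_gene_annotation()], [read_count_matrix()] and
#' [read_metadata()].
#'
#' @param cohort a `sim_cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of written paths.
#' @export
write_fixture <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok || file.access(dir, 2) != 0)
    stop("cannot write fixture: directory '", dir, "' is not writable")
  snp_dir <- file.path(dir, "snp_counts")
  dir.create(snp_dir, showWarnings = FALSE)
  paths <- character()
  cols <- c("contig", "position", "variantID", "refAllele", "altAllele",
            "refCount", "altCount", "totalCount")
  for (s in cohort$metadata$sample_id) {
    tab <- cohort$snp_counts[cohort$snp_counts$sample_id == s, cols,
                             with = FALSE]
    p <- file.path(snp_dir, paste0(s, ".tsv"))
    data.table::fwrite(tab, p, sep = "\t")
    paths <- c(paths, p)
  }
  ## GFF3 annotation: one gene + one exon feature per gene
  gff <- file.path(dir, "genes.gff3")
  g <- cohort$genes
  if (nrow(g) > 0) {
    gr <- GenomicRanges::GRanges(
      seqnames = rep(g$chrom, 2),
      ranges = IRanges::IRanges(rep(g$start, 2), rep(g$end, 2)),
      strand = "+",
      type = rep(c("gene", "exon"), each = nrow(g)),
      ID = c(g$gene_id, paste0(g$gene_id, ".exon1")),
      Parent = c(rep(NA_character_, nrow(g)), g$gene_id),
      gene_id = rep(g$gene_id, 2)
    )
    rtracklayer::export(gr, gff, format = "gff3")
  } else {
    writeLines("##gff-version 3", gff)
  }
  if (nrow(cohort$counts) > 0) {
    cnt <- cbind(data.table::data.table(gene_id = rownames(cohort$counts)),
                 data.table::as.data.table(cohort$counts))
  } else {
    cols <- c(list(gene_id = character()),
              stats::setNames(rep(list(integer()), ncol(cohort$counts)),
                              colnames(cohort$counts)))
    cnt <- data.table::as.data.table(cols)
  }
  data.table::fwrite(cnt, file.path(dir, "counts.tsv"), sep = "\t")
  data.table::fwrite(cohort$metadata, file.path(dir, "metadata.tsv"), sep = "\t")
  data.table::fwrite(cohort$truth$genes, file.path(dir, "truth_genes.tsv"),
                     sep = "\t")
  inh <- data.table::data.table(plant_id = rownames(cohort$truth$inherit),
                                cohort$truth$inherit)
  data.table::fwrite(inh, file.path(dir, "truth_inherit.tsv"), sep = "\t")
  invisible(c(paths, gff, file.path(dir, c("counts.tsv", "metadata.tsv",
                                           "truth_genes.tsv",
                                           "truth_inherit.tsv"))))
}
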