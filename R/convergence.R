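## Convergence between populations: overlap significance and effect-size
## concordance.

#' Upper-tail hypergeometric overlap test
#'
#' Probability of observing at least `x` genes in common between a list of
#' `K` significant genes (population 1) and `n` significant genes
#' (population 2) drawn from `N` assayed background genes, computed in log
#' space for numerical stability.
#'
#' @param N background genes assayed.
#' @param K significant genes in population 1.
#' @param n significant genes in population 2.
#' @param x observed overlap.
#' @return upper-tail p-value `P(X >= x)`.
#' @export
hypergeom_overlap <- function(N, K, n, x) {
  args <- c(N = N, K = K, n = n, x = x)
  if (any(args != round(args)) || any(args < 0))
    stop("N, K, n, x must be non-negative integers")
  if (K > N || n > N) stop("K and n must not exceed N")
  if (x > min(K, n)) stop("overlap x exceeds min(K, n)")
  if (x == 0) return(1)
  exp(stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Classify convergent genes between two populations
#'
#' A gene is convergent iff it is significant in both populations
#' (`lfsr < alpha` in each) and its posterior mean effects share the same
#' nonzero sign. Genes significant in both but with opposite signs are
#' flagged discordant.
#'
#' @param lfsr1,lfsr2 per-gene lfsr vectors for the two populations.
#' @param pm1,pm2 matching posterior mean effect vectors.
#' @param alpha significance threshold (default 0.05).
#' @param gene_ids optional gene identifiers.
#' @return `data.table` with per-gene `significant_1`, `significant_2`,
#'   `convergent`, `discordant` flags, plus attribute `"summary"` (counts
#'   `K`, `n`, `overlap`, `convergent`, `discordant`).
#' @export
classify_convergent <- function(lfsr1, lfsr2, pm1, pm2, alpha = 0.05,
                                gene_ids = NULL) {
  len <- length(lfsr1)
  if (length(lfsr2) != len || length(pm1) != len || length(pm2) != len)
    stop("input vectors have mismatched lengths")
  if (is.null(gene_ids)) gene_ids <- names(lfsr1)
  if (is.null(gene_ids)) gene_ids <- as.character(seq_len(len))
  sig1 <- !is.na(lfsr1) & lfsr1 < alpha
  sig2 <- !is.na(lfsr2) & lfsr2 < alpha
  same_sign <- sign(pm1) == sign(pm2) & sign(pm1) != 0
  conv <- sig1 & sig2 & !is.na(same_sign) & same_sign
  disc <- sig1 & sig2 & !conv
  out <- data.table::data.table(gene_id = gene_ids,
                                lfsr_1 = lfsr1, lfsr_2 = lfsr2,
                                pm_1 = pm1, pm_2 = pm2,
                                significant_1 = sig1, significant_2 = sig2,
                                convergent = conv, discordant = disc)
  attr(out, "summary") <- list(K = sum(sig1), n = sum(sig2),
                               overlap = sum(sig1 & sig2),
                               convergent = sum(conv),
                               discordant = sum(disc))
  out
}

#' Effect-size concordance between populations
#'
#' Pearson correlation of the posterior mean effects over all genes and
#' over a subset (typically the convergent genes); on convergence-enriched
#' data the subset correlation is expected to exceed the all-gene one.
#'
#' @param pm1,pm2 per-gene effect vectors.
#' @param subset logical or index vector selecting the subset (at least 3
#'   genes).
#' @return list: `r_all`, `r_subset`, `n_all`, `n_subset`. A zero-variance
#'   input yields `NA` with a warning.
#' @export
effect_concordance <- function(pm1, pm2, subset) {
  ok <- is.finite(pm1) & is.finite(pm2)
  safe_cor <- function(a, b) {
    if (length(a) < 3 || stats::sd(a) == 0 || stats::sd(b) == 0) {
      warning("zero variance or too few genes; correlation undefined")
      return(NA_real_)
    }
    stats::cor(a, b)
  }
  if (is.logical(subset)) subset <- which(subset)
  sub_ok <- intersect(subset, which(ok))
  if (length(sub_ok) < 3) stop("subset must contain at least 3 genes")
  list(r_all = safe_cor(pm1[ok], pm2[ok]),
       r_subset = safe_cor(pm1[sub_ok], pm2[sub_ok]),
       n_all = sum(ok), n_subset = length(sub_ok))
}
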