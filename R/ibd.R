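## Identity-by-descent classification between sibling plants of an F1
## family from shared heterozygous-SNP patterns.

#' Partition SNP positions into equal-count bins
#'
#' Divides the sorted SNP positions of one chromosome into `n_bins` bins
#' containing equal numbers of SNPs (sizes differ by at most 1). Boundaries
#' are half-open on position: bin i covers `[start_i, start_{i+1})`, with the
#' last bin closed at `+Inf`.
#'
#' @param positions sorted SNP positions of one chromosome.
#' @param n_bins number of bins (default 20).
#' @param chrom optional chromosome label for error messages.
#' @return `data.table` with `bin` (0-based), `start`, `end` (position of
#'   the first SNP of the next bin, or `Inf`), and `n_snps`.
#' @export
bin_snps_equal_count <- function(positions, n_bins = 20, chrom = NULL) {
  if (is.unsorted(positions)) positions <- sort(positions)
  n <- length(positions)
  if (n < n_bins)
    stop("chromosome ", if (!is.null(chrom)) chrom else "?",
         ": fewer SNPs (", n, ") than bins (", n_bins, ")")
  sizes <- rep(n %/% n_bins, n_bins)
  extra <- n %% n_bins
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  first <- cumsum(c(1L, sizes[-n_bins]))
  starts <- positions[first]
  ends <- c(starts[-1], Inf)
  data.table::data.table(bin = seq_len(n_bins) - 1L, start = starts,
                         end = ends, n_snps = sizes)
}

#' Shared heterozygous-site fraction of a bin
#'
#' For the heterozygous-site position sets of two samples restricted to one
#' bin, returns `|A intersect B| / min(|A|, |B|)`; `NA` if either set is
#' empty. Symmetric in its arguments.
#'
#' @param het_a,het_b position vectors of heterozygous sites in the bin.
#' @return fraction in `[0, 1]`, or `NA`.
#' @export
shared_het_fraction <- function(het_a, het_b) {
  a <- unique(het_a); b <- unique(het_b)
  if (length(a) == 0 || length(b) == 0) return(NA_real_)
  length(intersect(a, b)) / min(length(a), length(b))
}

#' Fit a two-component 1-D Gaussian mixture by EM
#'
#' Components are ordered by mean (component 2 has the higher mean) and the
#' returned per-point posteriors are for the higher-mean component.
#' Initialization: component means at the 25th/75th percentiles, both
#' variances at the overall variance, equal weights. Convergence is declared
#' when the log-likelihood improves by less than `tol`.
#'
#' @param values finite numeric values (at least `2*k`).
#' @param k number of components (only `k = 2` supported).
#' @param tol log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations; non-convergence gives a warning
#'   and the best fit found, flagged `converged = FALSE`.
#' @param var_floor lower bound on component variances.
#' @return list of class `"gmm1d"`: `means`, `vars`, `weights`, `posterior`
#'   (probability of the higher-mean component), `loglik` (trace),
#'   `converged`, `degenerate`.
#' @export
fit_gmm_1d <- function(values, k = 2, tol = 1e-8, max_iter = 1000,
                       var_floor = 1e-10) {
  stopifnot(k == 2)
  x <- values[is.finite(values)]
  n <- length(x)
  if (n < 2 * k) stop("need at least ", 2 * k, " finite values")
  if (stats::var(x) < var_floor) {
    ## all values (essentially) identical: mixture is unidentifiable
    return(structure(list(means = rep(mean(x), 2), vars = rep(0, 2),
                          weights = c(0.5, 0.5),
                          posterior = rep(0.5, n), loglik = numeric(),
                          converged = TRUE, degenerate = TRUE),
                     class = "gmm1d"))
  }
  mu <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
  sig2 <- rep(stats::var(x), 2)
  w <- c(0.5, 0.5)
  ll_trace <- numeric()
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    d1 <- stats::dnorm(x, mu[1], sqrt(sig2[1])) * w[1]
    d2 <- stats::dnorm(x, mu[2], sqrt(sig2[2])) * w[2]
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    g2 <- d2 / tot
    ll <- sum(log(tot))
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
    n2 <- sum(g2); n1 <- n - n2
    if (n1 < 1e-8 || n2 < 1e-8) break  # one component emptied out
    mu <- c(sum((1 - g2) * x) / n1, sum(g2 * x) / n2)
    sig2 <- pmax(var_floor,
                 c(sum((1 - g2) * (x - mu[1])^2) / n1,
                   sum(g2 * (x - mu[2])^2) / n2))
    w <- c(n1, n2) / n
  }
  if (!converged)
    warning("GMM EM did not converge in ", max_iter,
            " iterations; returning best fit found")
  ## order components so that index 2 is the higher-mean component
  if (mu[1] > mu[2]) {
    mu <- rev(mu); sig2 <- rev(sig2); w <- rev(w); g2 <- 1 - g2
  }
  structure(list(means = mu, vars = sig2, weights = w, posterior = g2,
                 loglik = ll_trace, converged = converged,
                 degenerate = FALSE),
            class = "gmm1d")
}

#' Classify bins from higher-mean-component posteriors
#'
#' A bin is `IBD` if its posterior probability of belonging to the
#' higher-mean (shared-haplotype) component is strictly above `hi`,
#' `not-IBD` if strictly below `lo`, otherwise `ambiguous`. Missing
#' posteriors are `ambiguous`.
#'
#' @param posteriors posterior probabilities in `[0, 1]` (NA allowed).
#' @param hi,lo strict thresholds (defaults 0.90 and 0.10).
#' @return factor with levels `IBD`, `not-IBD`, `ambiguous`.
#' @export
classify_bins <- function(posteriors, hi = 0.90, lo = 0.10) {
  cls <- rep("ambiguous", length(posteriors))
  cls[!is.na(posteriors) & posteriors > hi] <- "IBD"
  cls[!is.na(posteriors) & posteriors < lo] <- "not-IBD"
  factor(cls, levels = c("IBD", "not-IBD", "ambiguous"))
}

#' Classify IBD bins between two samples of one family
#'
#' End-to-end IBD classification for one sample pair: bins each chromosome
#' into `n_bins` equal-SNP bins using the supplied genome-wide SNP
#' positions, computes the shared heterozygous-site fraction per bin from
#' the two samples' heterozygous calls, pools the fractions across
#' chromosomes, fits a two-component Gaussian mixture and classifies each
#' bin. Bins where either sample has no heterozygous site are excluded from
#' the mixture fit and labeled `ambiguous`.
#'
#' Heterozygous calls are taken to be the SNPs passing the per-sample ASE
#' filters ([filter_ase_snps()]): a site with both alleles credibly observed
#' is heterozygous in that sample.
#'
#' @param het_a,het_b `data.table`s with `contig` and `position` columns:
#'   heterozygous sites of the two samples.
#' @param snp_positions `data.table` with `contig`, `position`: the full SNP
#'   panel used to define bins (e.g., all WGS-derived SNPs).
#' @param n_bins bins per chromosome.
#' @param hi,lo posterior thresholds for [classify_bins()].
#' @return `data.table`: `contig`, `bin`, `start`, `end`, `n_het_a`,
#'   `n_het_b`, `f` (shared-het fraction), `posterior`, `class`; the fitted
#'   mixture is attached as attribute `"gmm"`.
#' @export
ibd_classify_pair <- function(het_a, het_b, snp_positions, n_bins = 20,
                              hi = 0.90, lo = 0.10) {
  chroms <- sort(unique(snp_positions$contig))
  out <- vector("list", length(chroms))
  for (i in seq_along(chroms)) {
    ch <- chroms[i]
    pos <- sort(snp_positions$position[snp_positions$contig == ch])
    bins <- bin_snps_equal_count(pos, n_bins, chrom = ch)
    a <- het_a$position[het_a$contig == ch]
    b <- het_b$position[het_b$contig == ch]
    idx_a <- findInterval(a, bins$start)
    idx_b <- findInterval(b, bins$start)
    f <- n_a <- n_b <- rep(NA_real_, n_bins)
    for (j in seq_len(n_bins)) {
      aj <- a[idx_a == j]; bj <- b[idx_b == j]
      n_a[j] <- length(unique(aj)); n_b[j] <- length(unique(bj))
      f[j] <- shared_het_fraction(aj, bj)
    }
    out[[i]] <- data.table::data.table(contig = ch, bins,
                                       n_het_a = as.integer(n_a),
                                       n_het_b = as.integer(n_b), f = f)
  }
  tab <- data.table::rbindlist(out)
  usable <- which(!is.na(tab$f))
  tab$posterior <- NA_real_
  gmm <- NULL
  if (length(usable) >= 4) {
    gmm <- fit_gmm_1d(tab$f[usable])
    tab$posterior[usable] <- gmm$posterior
    if (isTRUE(gmm$degenerate)) tab$posterior[usable] <- NA_real_
  }
  tab$class <- classify_bins(tab$posterior, hi = hi, lo = lo)
  attr(tab, "gmm") <- gmm
  tab
}
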