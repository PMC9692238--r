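## Cell-composition assessment by weighted marker-gene projection scores.

#' Packaged example marker sets (synthetic)
#'
#' A small synthetic marker table for seven leaf cell populations (five
#' mesophyll-like, two bundle-sheath-like), with weights drawn once at a
#' fixed seed and gene ids matching the simulator's naming. It illustrates
#' the scoring interface; real reference marker sets (e.g., from
#' single-cell data of the target tissue) are user-supplied in the same
#' three-column format.
#'
#' @return `data.table` with columns `population`, `gene_id`, `weight`.
#' @export
example_marker_sets <- function() {
  data.table::fread(system.file("extdata", "synthetic_leaf_markers.tsv",
                                package = "dasepipe"), sep = "\t")
}

#' Marker-gene projection scores per sample
#'
#' For each cell population c with marker genes g and weights `w_gc`
#' (typically the marker's average log2 fold change in the reference
#' single-cell data), the sample score is the weighted sum of mean-centered
#' expression: `score_sc = sum_g w_gc * (x_gs - mean_s' x_gs')`. Scores are
#' relative (they sum to ~0 over samples per population) and do not assume
#' that all cell populations present in the samples are represented in the
#' reference.
#'
#' @param expr genes x samples expression matrix on the log2 scale (e.g.,
#'   log2-CPM from [voom_counts()]).
#' @param markers `data.table`/data.frame with columns `population`,
#'   `gene_id`, `weight`. Markers absent from `expr` are dropped and
#'   tallied in attribute `"dropped_markers"`; a population with no assayed
#'   marker yields an all-`NA` column with a warning.
#' @return samples x populations score matrix.
#' @export
projection_scores <- function(expr, markers) {
  pops <- sort(unique(markers$population))
  centered <- expr - rowMeans(expr)
  out <- matrix(NA_real_, ncol(expr), length(pops),
                dimnames = list(colnames(expr), pops))
  dropped <- integer(length(pops)); names(dropped) <- pops
  for (p in pops) {
    mk <- markers[markers$population == p, ]
    have <- mk$gene_id %in% rownames(expr)
    dropped[p] <- sum(!have)
    if (!any(have)) {
      warning("marker set '", p, "' has no assayed genes; scores set to NA")
      next
    }
    mk <- mk[have, ]
    out[, p] <- as.vector(crossprod(centered[mk$gene_id, , drop = FALSE],
                                    mk$weight))
  }
  attr(out, "dropped_markers") <- dropped
  out
}

#' Permutation null for the projection-score variance
#'
#' Recomputes the scores `n_perm` times after reassigning the marker gene
#' identities uniformly at random (without replacement) to genes from the
#' expressed pool, keeping the weights. The statistic is the total variance
#' of the score matrix across samples; the empirical p-value is
#' `(1 + #(null >= observed)) / (n_perm + 1)`.
#'
#' @inheritParams projection_scores
#' @param n_perm number of permutations (default 200; below 20 gives a
#'   warning about an unstable p-value).
#' @param pool optional character vector of gene ids to draw from (default
#'   all rows of `expr`, i.e., the expression-filtered genes).
#' @param seed integer seed for the permutation draws.
#' @return list: `statistic` (observed total score variance), `null`
#'   (vector of `n_perm` null statistics), `p` (empirical p-value).
#' @export
permutation_null <- function(expr, markers, n_perm = 200, pool = NULL,
                             seed = 1) {
  if (n_perm < 20) warning("n_perm < 20: the empirical p-value is unstable")
  if (is.null(pool)) pool <- rownames(expr)
  n_mark <- length(unique(markers$gene_id))
  if (length(pool) < n_mark)
    stop("not enough genes in the pool to reassign ", n_mark, " markers")
  score_var <- function(m) {
    sc <- suppressWarnings(projection_scores(expr, m))
    sum(apply(sc, 2, stats::var), na.rm = TRUE)
  }
  observed <- score_var(markers)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  ids <- unique(markers$gene_id)
  null <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    repl <- sample(pool, n_mark)
    m2 <- data.table::as.data.table(markers)
    m2$gene_id <- repl[match(m2$gene_id, ids)]
    null[i] <- score_var(m2)
  }
  list(statistic = observed, null = null,
       p = (1 + sum(null >= observed)) / (n_perm + 1))
}

#' PCA of the projection-score matrix
#'
#' Centered principal component analysis of the samples x populations score
#' matrix, with a deterministic sign convention (the largest-magnitude
#' loading of each component is positive).
#'
#' @param scores samples x populations matrix from [projection_scores()].
#' @param n_pcs number of components to return.
#' @return list: `coords` (samples x n_pcs), `loadings`,
#'   `var_explained` (fraction per returned PC), `zero_variance` flag.
#' @export
score_pca <- function(scores, n_pcs = 2) {
  sc <- scores[, colSums(is.na(scores)) == 0, drop = FALSE]
  if (ncol(sc) < 2) stop("need at least 2 scored populations for a PCA")
  ctr <- scale(sc, center = TRUE, scale = FALSE)
  sv <- svd(ctr)
  totvar <- sum(sv$d^2)
  zero <- totvar < 1e-12
  n_pcs <- min(n_pcs, ncol(sc))
  loadings <- sv$v[, seq_len(n_pcs), drop = FALSE]
  for (k in seq_len(n_pcs)) {
    i <- which.max(abs(loadings[, k]))
    if (loadings[i, k] < 0) { loadings[, k] <- -loadings[, k]
      sv$u[, k] <- -sv$u[, k] }
  }
  coords <- sv$u[, seq_len(n_pcs), drop = FALSE] %*%
    diag(sv$d[seq_len(n_pcs)], n_pcs)
  dimnames(coords) <- list(rownames(sc), paste0("PC", seq_len(n_pcs)))
  rownames(loadings) <- colnames(sc)
  colnames(loadings) <- paste0("PC", seq_len(n_pcs))
  list(coords = coords, loadings = loadings,
       var_explained = if (zero) rep(0, n_pcs) else
         sv$d[seq_len(n_pcs)]^2 / totvar,
       zero_variance = zero)
}
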