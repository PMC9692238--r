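## Shared modeling engine: design construction, count-mode voom, the
## ASE-adapted variance trend, precision-weighted least squares and
## empirical-Bayes moderation.

#' Build the design matrix for the elevation-divergence model
#'
#' Columns: intercept; block dummies (only when the metadata has more than
#' one block, i.e., the two-block highland site); sampling-team dummies; a
#' cubic orthogonal polynomial of field sampling order fit separately
#' within each team (sampling time proxy); a population main effect; one
#' highland-vs-lowland contrast per population (`elev_<population>`); and a
#' within-population-centered latitude slope per population
#' (`lat_<population>`). Optionally, cell-composition covariate columns are
#' appended.
#'
#' The elevation contrast for each population is directly extractable by
#' its named column: `elev_Mexico` is the average highland-minus-lowland
#' difference among that population's samples, holding the nuisance terms
#' fixed.
#'
#' @param metadata sample table with `sample_id`, `population`, `elevation`
#'   (`"Highland"`/`"Lowland"`), `latitude`, `block`, `team`, `field_order`.
#' @param cell_scores optional samples x k numeric matrix of covariates
#'   (rows matched to `metadata$sample_id` by rowname).
#' @param poly_degree degree of the per-team sampling-order polynomial
#'   (reduced per team when a team has too few distinct order values).
#' @return numeric design matrix, one row per sample (rownames =
#'   sample_id). Errors if the matrix is column-rank deficient, listing the
#'   aliased columns.
#' @export
build_design <- function(metadata, cell_scores = NULL, poly_degree = 3) {
  n <- nrow(metadata)
  X <- matrix(1, n, 1, dimnames = list(metadata$sample_id, "(Intercept)"))
  blocks <- sort(unique(metadata$block))
  if (length(blocks) > 1) {
    for (b in blocks[-1])
      X <- cbind(X, as.numeric(metadata$block == b))
    colnames(X)[(ncol(X) - length(blocks) + 2):ncol(X)] <-
      paste0("block", blocks[-1])
  }
  teams <- sort(unique(metadata$team))
  if (length(teams) > 1) {
    for (tm in teams[-1])
      X <- cbind(X, as.numeric(metadata$team == tm))
    colnames(X)[(ncol(X) - length(teams) + 2):ncol(X)] <-
      paste0("team", teams[-1])
  }
  ## per-team orthogonal polynomial of field order (zero outside the team)
  for (tm in teams) {
    idx <- metadata$team == tm
    ord <- metadata$field_order[idx]
    deg <- min(poly_degree, length(unique(ord)) - 1L)
    if (deg < 1) next
    P <- stats::poly(ord, degree = deg)
    M <- matrix(0, n, deg,
                dimnames = list(NULL, paste0("team", tm, "_order", seq_len(deg))))
    M[idx, ] <- P
    X <- cbind(X, M)
  }
  pops <- sort(unique(metadata$population))
  if (length(pops) > 1) {
    for (p in pops[-1])
      X <- cbind(X, as.numeric(metadata$population == p))
    colnames(X)[(ncol(X) - length(pops) + 2):ncol(X)] <- paste0("pop", pops[-1])
  }
  for (p in pops) {
    X <- cbind(X, as.numeric(metadata$population == p &
                               metadata$elevation == "Highland"))
    colnames(X)[ncol(X)] <- paste0("elev_", p)
  }
  for (p in pops) {
    idx <- metadata$population == p
    lat <- numeric(n)
    lat[idx] <- metadata$latitude[idx] - mean(metadata$latitude[idx])
    X <- cbind(X, lat)
    colnames(X)[ncol(X)] <- paste0("lat_", p)
  }
  if (!is.null(cell_scores)) {
    cs <- as.matrix(cell_scores)
    if (!is.null(rownames(cs))) cs <- cs[metadata$sample_id, , drop = FALSE]
    if (is.null(colnames(cs))) colnames(cs) <- paste0("cellscore", seq_len(ncol(cs)))
    X <- cbind(X, cs)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  X
}

#' Count-mode voom: log2-CPM and precision weights
#'
#' Standard voom transform for the total-expression analysis:
#' `log2((count + 0.5) / (libsize * factor + 1) * 1e6)`, a lowess trend of
#' sqrt residual SD versus average log2 count, and per-observation weights
#' equal to the predicted standard deviation to the power -4 (inverse
#' predicted variance). Wraps `limma::voom`.
#'
#' @param counts filtered genes x samples count matrix.
#' @param factors TMM normalization factors
#'   (default [tmm_normalization_factors()]).
#' @param design design matrix from [build_design()].
#' @param span lowess span.
#' @return list with `E` (log2-CPM matrix), `weights`, and the underlying
#'   `EList`.
#' @export
voom_counts <- function(counts, factors = NULL, design, span = 0.5) {
  if (nrow(counts) - 0 < 2) stop("too few genes for a variance trend")
  if (nrow(design) != ncol(counts)) stop("design/count dimension mismatch")
  if (ncol(counts) <= ncol(design) + 1)
    stop("fewer than 2 residual degrees of freedom")
  if (is.null(factors)) factors <- tmm_normalization_factors(counts)
  v <- limma::voom(counts, design = design,
                   lib.size = colSums(counts) * factors, span = span)
  list(E = v$E, weights = v$weights, elist = v)
}

#' ASE-adapted voom: precision weights for log2ASE ratios
#'
#' The precision of a log2ASE ratio varies strongly with the number of
#' ASE-informative reads behind it. This routine (1) fits the design to
#' each gene's log2ASE by ordinary least squares with missing cells
#' excluded, (2) fits a lowess trend of the square root of the residual SD
#' against the gene's average log2 normalized total ASE count, (3) predicts
#' each observation's sqrt-SD by interpolating the trend at that
#' observation's own log2 normalized total count, and (4) sets the
#' observation weight to predicted^(-4) (inverse predicted variance).
#' Cells with zero counts from either allele carry no information about the
#' allelic ratio (unlike a ratio of zero, which asserts equality) and get
#' weight exactly 0.
#'
#' Normalization: per-sample totals are scaled by the sample's total
#' ASE-informative library size, times 1e6, with a +0.5 offset before log2.
#'
#' @param log2ase genes x samples matrix of log2ASE ratios (`NA` = missing).
#' @param total matching matrix of ASE-informative totals (landrace + B73).
#' @param design design matrix.
#' @param span lowess span (default 0.5, 3 robustifying iterations).
#' @param min_df genes with residual df below this are dropped from the
#'   trend fit (their observations still get weights from the trend).
#' @return list: `weights` (genes x samples, 0 at missing cells), `trend`
#'   (list with knot `x`, `y` on the sqrt-SD scale), `sigma`, `df_residual`
#'   per gene, and `xobs` (the per-observation log2 normalized totals).
#' @export
ase_voom <- function(log2ase, total, design, span = 0.5, min_df = 1) {
  stopifnot(identical(dim(log2ase), dim(total)),
            nrow(design) == ncol(log2ase))
  G <- nrow(log2ase)
  lib <- colSums(total)
  xobs <- log2(sweep(total + 0.5, 2, lib, "/") * 1e6)
  sigma <- df_res <- rep(NA_real_, G)
  for (g in seq_len(G)) {
    ok <- which(!is.na(log2ase[g, ]))
    if (length(ok) <= ncol(design)) next
    f <- stats::lm.fit(design[ok, , drop = FALSE], log2ase[g, ok])
    dfr <- length(ok) - f$rank
    if (dfr < min_df) next
    sigma[g] <- sqrt(sum(f$residuals^2) / dfr)
    df_res[g] <- dfr
  }
  usable <- which(!is.na(sigma) & sigma > 0)
  if (length(usable) < 10)
    stop("too few genes with a positive residual SD to fit a variance trend")
  n_drop <- sum(is.na(sigma))
  if (n_drop > 0)
    warning(n_drop, " gene(s) had insufficient residual df for the ",
            "variance trend and were excluded from it")
  xbar <- rowMeans(xobs)
  lo <- stats::lowess(xbar[usable], sqrt(sigma[usable]), f = span, iter = 3)
  pred <- stats::approx(lo$x, lo$y, xout = as.vector(xobs), rule = 2,
                        ties = "ordered")$y
  pred <- pmax(pred, 1e-6)
  w <- matrix(pred^(-4), G, ncol(log2ase), dimnames = dimnames(log2ase))
  w[is.na(log2ase)] <- 0
  list(weights = w, trend = list(x = lo$x, y = lo$y), sigma = sigma,
       df_residual = df_res, xobs = xobs)
}

#' Per-gene precision-weighted least squares
#'
#' Fits `y_g ~ design` by weighted least squares for every gene, treating
#' zero-weight cells as missing. Genes with fewer than `rank + 2` positively
#' weighted observations, or whose weighted normal equations are singular
#' (e.g., a needed design column is all zero-weight), are dropped with a
#' warning and recorded in attribute `"dropped"`.
#'
#' @param y genes x samples response matrix (`NA` allowed where weight 0).
#' @param design design matrix.
#' @param weights genes x samples non-negative weight matrix (default all 1,
#'   in which case the fit is ordinary least squares).
#' @return list of class `"weighted_fit"`: `coefficients`,
#'   `stdev.unscaled` (both genes x p), `sigma`, `df.residual`, plus the
#'   inputs' dimnames.
#' @export
fit_weighted_lm <- function(y, design, weights = NULL) {
  if (is.null(weights)) weights <- matrix(1, nrow(y), ncol(y))
  stopifnot(identical(dim(y), dim(weights)), nrow(design) == ncol(y))
  G <- nrow(y); p <- ncol(design)
  coef <- su <- matrix(NA_real_, G, p,
                       dimnames = list(rownames(y), colnames(design)))
  sigma <- dfres <- rep(NA_real_, G)
  dropped <- character()
  for (g in seq_len(G)) {
    w <- weights[g, ]
    ok <- which(w > 0 & !is.na(y[g, ]))
    if (length(ok) < p + 2) { dropped <- c(dropped, rownames(y)[g]); next }
    Xg <- design[ok, , drop = FALSE]
    f <- tryCatch(stats::lm.wfit(Xg, y[g, ok], w[ok]), error = function(e) NULL)
    if (is.null(f) || f$rank < p) { dropped <- c(dropped, rownames(y)[g]); next }
    XtWX <- crossprod(Xg * sqrt(w[ok]))
    inv <- tryCatch(chol2inv(chol(XtWX)), error = function(e) NULL)
    if (is.null(inv)) { dropped <- c(dropped, rownames(y)[g]); next }
    coef[g, ] <- f$coefficients
    su[g, ] <- sqrt(diag(inv))
    dfres[g] <- length(ok) - p
    sigma[g] <- sqrt(sum(w[ok] * f$residuals^2) / dfres[g])
  }
  if (length(dropped) > 0)
    warning(length(dropped), " gene(s) dropped: too few weighted ",
            "observations or singular weighted fit")
  keep <- !is.na(sigma)
  out <- list(coefficients = coef[keep, , drop = FALSE],
              stdev.unscaled = su[keep, , drop = FALSE],
              sigma = sigma[keep], df.residual = dfres[keep],
              design = design)
  attr(out, "dropped") <- dropped
  class(out) <- "weighted_fit"
  out
}

#' Posterior (moderated) residual variance
#'
#' The empirical-Bayes pooled variance
#' \eqn{s^2_{post} = (d_0 s_0^2 + d_g s_g^2) / (d_0 + d_g)}, with the
#' conventional limits: `d0 = Inf` gives `s0²` for every gene and `d0 = 0`
#' returns the unmoderated `s²`.
#'
#' @param s2 per-gene residual variances.
#' @param df per-gene residual degrees of freedom.
#' @param d0 prior degrees of freedom (may be `Inf`).
#' @param s02 prior variance.
#' @return vector of posterior variances.
#' @export
posterior_variance <- function(s2, df, d0, s02) {
  if (is.infinite(d0)) return(rep(s02, length(s2)))
  if (d0 == 0) return(s2)
  (d0 * s02 + df * s2) / (d0 + df)
}

#' Empirical-Bayes moderation of a weighted fit
#'
#' Estimates the prior df `d0` and prior variance `s0²` by fitting a scaled
#' F-distribution to the per-gene residual variances (moment matching on
#' `log s²`, via `limma::squeezeVar`), pools each gene's variance with
#' [posterior_variance()], and forms moderated t-statistics
#' `t = beta / (sqrt(s2.post) * stdev.unscaled)` on `d0 + d_g` degrees of
#' freedom. When the moment estimator finds no excess variability among the
#' `log s²` (negative trigamma target), `d0` is infinite and all variances
#' shrink to `s0²`.
#'
#' @param fit a `"weighted_fit"` from [fit_weighted_lm()] (needs at least
#'   10 genes).
#' @return the fit with added elements `df.prior` (d0), `s2.prior` (s0²),
#'   `s2.post`, `t` (moderated t matrix), `df.total`, `p.value`.
#' @export
ebayes_moderate <- function(fit) {
  stopifnot(inherits(fit, "weighted_fit"))
  if (length(fit$sigma) < 10)
    stop("empirical-Bayes moderation needs at least 10 genes")
  sv <- limma::squeezeVar(fit$sigma^2, fit$df.residual)
  fit$df.prior <- sv$df.prior
  fit$s2.prior <- sv$var.prior
  fit$s2.post <- posterior_variance(fit$sigma^2, fit$df.residual,
                                    sv$df.prior, sv$var.prior)
  fit$t <- fit$coefficients / (sqrt(fit$s2.post) * fit$stdev.unscaled)
  fit$df.total <- fit$df.residual + sv$df.prior
  fit$p.value <- 2 * stats::pt(-abs(fit$t), df = fit$df.total)
  fit
}

#' Extract per-population elevation effects from a moderated fit
#'
#' Pulls the highland-vs-lowland contrast column of each population
#' (`elev_<population>`) with its moderated standard error
#' `sqrt(s2.post) * stdev.unscaled`.
#'
#' @param fit a moderated `"weighted_fit"` (after [ebayes_moderate()]).
#' @return `data.table`: `gene_id`, `population`, `beta`, `se`, `t`, `df`,
#'   `p`.
#' @export
extract_elevation_effects <- function(fit) {
  cols <- grep("^elev_", colnames(fit$coefficients), value = TRUE)
  if (length(cols) == 0)
    stop("no 'elev_<population>' contrast column in the fit; ",
         "was the design built with build_design()?")
  if (is.null(fit$s2.post))
    stop("fit has not been moderated; run ebayes_moderate() first")
  out <- lapply(cols, function(cl) {
    data.table::data.table(
      gene_id = rownames(fit$coefficients),
      population = sub("^elev_", "", cl),
      beta = fit$coefficients[, cl],
      se = sqrt(fit$s2.post) * fit$stdev.unscaled[, cl],
      t = fit$t[, cl],
      df = fit$df.total,
      p = fit$p.value[, cl])
  })
  data.table::rbindlist(out)
}
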