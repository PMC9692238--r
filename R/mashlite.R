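## Multivariate adaptive shrinkage meta-analysis across conditions:
## mixture-of-multivariate-normals prior with a scale grid, EM mixture
## weights, posterior effects and local false sign rates (lfsr).

.mash_impute <- function(Bhat, Shat, big_se = 1e6) {
  miss <- is.na(Bhat) | is.na(Shat) | !(Shat > 0)
  Bhat[miss] <- 0
  Shat[miss] <- big_se
  list(Bhat = Bhat, Shat = Shat, missing = miss)
}

#' Estimate the residual correlation among conditions
#'
#' Empirical correlation of z-scores (`Bhat/Shat`) over genes whose
#' observed `|z|` is below `z_thresh` in every condition (approximately
#' null genes), shrunk toward the identity by `lambda`. This is a
#' simplified moment analogue of the EM residual-correlation estimator used
#' with full mash fits.
#'
#' @param Bhat,Shat genes x conditions effect and SE matrices (`NA` =
#'   missing).
#' @param z_thresh null-gene z cutoff (default 2).
#' @param lambda shrinkage toward the identity (default 0.05).
#' @param min_genes minimum qualifying genes; below this the identity is
#'   returned with a warning.
#' @return conditions x conditions positive-definite correlation matrix.
#' @export
estimate_residual_correlation <- function(Bhat, Shat, z_thresh = 2,
                                          lambda = 0.05, min_genes = 50) {
  R <- ncol(Bhat)
  z <- Bhat / Shat
  ok <- rowSums(!is.finite(z) | abs(z) >= z_thresh) == 0
  if (sum(ok) < min_genes) {
    warning("fewer than ", min_genes, " near-null genes; ",
            "returning the identity residual correlation")
    return(diag(R))
  }
  C <- stats::cor(z[ok, , drop = FALSE])
  C <- (1 - lambda) * C + lambda * diag(R)
  (C + t(C)) / 2
}

.normalize_cov <- function(U) {
  m <- max(diag(U))
  if (m > 0) U / m else U
}

#' Canonical covariance shapes
#'
#' Identity (independent effects), one singleton per condition (an effect
#' in only that condition), equal effects (all-ones), and heterogeneous
#' shared effects (unit diagonal, off-diagonal 0.25/0.5/0.75). Duplicate
#' shapes are removed (for `R = 1` the set collapses to a single scalar 1).
#' The point-mass null is handled separately by the fitting routines.
#'
#' @param R number of conditions.
#' @return named list of R x R PSD matrices with unit maximum diagonal.
#' @export
mash_canonical_covariances <- function(R) {
  covs <- list(identity = diag(R))
  for (r in seq_len(R)) {
    U <- matrix(0, R, R); U[r, r] <- 1
    covs[[paste0("singleton_", r)]] <- U
  }
  covs[["equal_effects"]] <- matrix(1, R, R)
  for (rho in c(0.25, 0.5, 0.75)) {
    U <- matrix(rho, R, R); diag(U) <- 1
    covs[[paste0("het_", rho)]] <- U
  }
  keys <- vapply(covs, function(U) paste(signif(U, 10), collapse = ","), "")
  covs[!duplicated(keys)]
}

#' Data-driven covariance shapes from strong signals
#'
#' Selects strong genes (observed `|z| > z_strong` in at least one
#' condition, a first-pass proxy for signals that would be significant
#' after fitting), takes the SVD of their z-score matrix, and returns one
#' rank-1 covariance per leading principal component plus the rank-`n_pcs`
#' reconstruction, each normalized to unit maximum diagonal.
#'
#' @inheritParams estimate_residual_correlation
#' @param z_strong strong-gene z cutoff (default 3.3).
#' @param n_pcs number of principal components (default `min(3, R)`).
#' @return named list of PSD matrices; empty (with a warning) when fewer
#'   than `n_pcs` strong genes exist.
#' @export
mash_data_driven_covariances <- function(Bhat, Shat, z_strong = 3.3,
                                         n_pcs = min(3L, ncol(Bhat))) {
  z <- Bhat / Shat
  z[!is.finite(z)] <- 0
  strong <- which(apply(abs(z), 1, max) > z_strong)
  if (length(strong) < n_pcs) {
    warning("fewer than ", n_pcs, " strong genes; ",
            "using canonical covariances only")
    return(list())
  }
  Z <- z[strong, , drop = FALSE]
  sv <- svd(Z, nu = 0)
  n_pcs <- min(n_pcs, sum(sv$d > 1e-8))
  covs <- list()
  for (p in seq_len(n_pcs)) {
    U <- (sv$d[p]^2 / nrow(Z)) * tcrossprod(sv$v[, p])
    covs[[paste0("pca_", p)]] <- .normalize_cov(U)
  }
  Vp <- sv$v[, seq_len(n_pcs), drop = FALSE]
  Ur <- Vp %*% diag(sv$d[seq_len(n_pcs)]^2 / nrow(Z),
                    n_pcs) %*% t(Vp)
  covs[[paste0("pca_rank", n_pcs)]] <- .normalize_cov(Ur)
  covs
}

#' Full covariance list (canonical + data-driven)
#' @inheritParams mash_data_driven_covariances
#' @return named list of PSD matrices with unit maximum diagonal.
#' @export
build_covariances <- function(Bhat, Shat, z_strong = 3.3,
                              n_pcs = min(3L, ncol(Bhat))) {
  c(mash_canonical_covariances(ncol(Bhat)),
    mash_data_driven_covariances(Bhat, Shat, z_strong, n_pcs))
}

#' Scale grid for the shrinkage prior
#'
#' Geometric grid of prior effect variances from `(min(Shat)/10)^2` to
#' `(4 * max|Bhat|)^2` with ratio 2, the adaptive-shrinkage convention of
#' spanning from well below the measurement error to well above the
#' largest observed effect.
#'
#' @inheritParams estimate_residual_correlation
#' @return numeric vector of prior variances (log2-squared units).
#' @export
mash_grid <- function(Bhat, Shat) {
  ok <- is.finite(Bhat) & is.finite(Shat) & Shat > 0 & Shat < 1e5
  if (!any(ok)) stop("no observed effects to build a scale grid from")
  lo <- (min(Shat[ok]) / 10)^2
  hi <- (4 * max(abs(Bhat[ok]), min(Shat[ok]))) ^ 2
  n <- max(1L, ceiling(log2(hi / lo)) + 1L)
  grid <- lo * 2^(seq_len(n) - 1)
  grid
}

.mash_components <- function(Ulist, omegas) {
  c("null", as.vector(t(outer(names(Ulist), signif(omegas, 4),
                              paste, sep = ";omega="))))
}

#' Fit the mixture weights by EM
#'
#' The marginal likelihood of gene j under component (k, w) is the
#' multivariate normal density of `Bhat_j` with mean 0 and covariance
#' `V_j + w * U_k`, where `V_j = diag(Shat_j) C diag(Shat_j)`; the null
#' component has covariance `V_j`. Component likelihoods are computed once;
#' EM then updates only the mixture weights, by default with a null-biased
#' prior (Dirichlet pseudo-count 10 on the null) so that sparse
#' alternatives are not over-weighted. Missing conditions enter as
#' `Bhat = 0, Shat = 1e6` (no information).
#'
#' @param Bhat,Shat genes x conditions matrices (`NA` = missing).
#' @param Ulist named list of covariance shapes (see [build_covariances()]).
#' @param omegas scale grid (see [mash_grid()]).
#' @param C residual correlation (see [estimate_residual_correlation()]).
#' @param null_biased use the null-biased prior (default `TRUE`).
#' @param tol convergence tolerance on the per-gene mean penalized
#'   log-likelihood.
#' @param max_iter maximum EM iterations.
#' @return list: `pi` (named weights, null first), `loglik` trace, `LL`
#'   (gene x component log-likelihood matrix), `excluded` (genes with
#'   non-finite likelihoods, removed before fitting).
#' @export
fit_mixture_em <- function(Bhat, Shat, Ulist, omegas, C,
                           null_biased = TRUE, tol = 1e-6, max_iter = 1000) {
  imp <- .mash_impute(Bhat, Shat)
  LL <- .mash_loglik_cpp(imp$Bhat, imp$Shat, C, unname(Ulist), omegas)
  bad <- which(apply(LL, 1, function(r) all(!is.finite(r))))
  if (length(bad) > 0) {
    warning(length(bad), " gene(s) with non-finite likelihoods excluded: ",
            paste(utils::head(rownames(Bhat)[bad], 5), collapse = ", "))
    LLf <- LL[-bad, , drop = FALSE]
  } else LLf <- LL
  J <- nrow(LLf); P <- ncol(LLf)
  lambda <- rep(1, P)
  if (null_biased) lambda[1] <- 10
  pi_vec <- rep(1 / P, P)
  shift <- apply(LLf, 1, max)
  L <- exp(LLf - shift)
  obj_old <- -Inf
  trace <- numeric()
  for (it in seq_len(max_iter)) {
    num <- sweep(L, 2, pi_vec, "*")
    denom <- rowSums(num)
    obj <- sum(log(denom) + shift) + sum((lambda - 1) * log(pmax(pi_vec, 1e-300)))
    trace <- c(trace, obj)
    if (is.finite(obj_old) && abs(obj - obj_old) < tol * J) break
    obj_old <- obj
    gam <- colSums(num / denom)
    w <- gam + lambda - 1
    pi_vec <- pmax(w, 0) / sum(pmax(w, 0))
  }
  ## Frank-Wolfe refinement: EM moves vanishingly slowly along directions
  ## where components are near-duplicates (e.g., the null versus the
  ## smallest grid scales). Conditional-gradient steps with exact line
  ## search resolve those ties toward the penalized-likelihood optimum.
  fobj <- function(p) sum(log(pmax(L %*% p, 1e-300)) + shift) +
    sum((lambda - 1) * log(pmax(p, 1e-300)))
  for (it in seq_len(2000)) {
    mix <- pmax(as.vector(L %*% pi_vec), 1e-300)
    grad <- as.vector(crossprod(L, 1 / mix)) + (lambda - 1) / pmax(pi_vec, 1e-12)
    s <- which.max(grad)
    fw_gap <- grad[s] - sum(grad * pi_vec)
    if (fw_gap < tol * J) break
    active <- which(pi_vec > 0)
    v <- active[which.min(grad[active])]
    if (s == v) break
    if (pi_vec[v] < 1e-8) {     # negligible mass: prune outright
      pi_vec[s] <- pi_vec[s] + pi_vec[v]
      pi_vec[v] <- 0
      next
    }
    f0 <- fobj(pi_vec)
    ls <- stats::optimize(function(d) {
      p <- pi_vec; p[v] <- p[v] - d; p[s] <- p[s] + d; fobj(p)
    }, c(0, pi_vec[v]), maximum = TRUE, tol = 1e-9)
    p_full <- pi_vec
    p_full[s] <- p_full[s] + p_full[v]; p_full[v] <- 0
    f_full <- fobj(p_full)
    if (max(ls$objective, f_full) <= f0) break
    if (f_full >= ls$objective) {
      pi_vec <- p_full
      trace <- c(trace, f_full)
    } else {
      d <- ls$maximum
      pi_vec[v] <- pi_vec[v] - d
      pi_vec[s] <- pi_vec[s] + d
      trace <- c(trace, ls$objective)
    }
  }
  names(pi_vec) <- .mash_components(Ulist, omegas)
  list(pi = pi_vec, loglik = trace, LL = LL,
       excluded = if (length(bad)) rownames(Bhat)[bad] else character())
}

#' Posterior effects and local false sign rates
#'
#' For each gene, the posterior over the true effect vector is the mixture
#' of multivariate-normal conditionals weighted by the component
#' responsibilities. Returns the mixture posterior mean and SD per
#' condition and the local false sign rate
#' `lfsr_r = min(P(b_r <= 0 | data), P(b_r >= 0 | data))`, with posterior
#' point mass at zero counted in both terms (so `pi_null = 1` gives
#' `lfsr = 1`). Cells that were missing in the input are set back to `NA`;
#' the per-gene overall lfsr is the minimum over the gene's observed
#' conditions.
#'
#' @inheritParams fit_mixture_em
#' @param pi mixture weights (null first, then U-major over the grid), as
#'   returned by [fit_mixture_em()].
#' @param LL optional precomputed log-likelihood matrix.
#' @return list of class `"mash_result"`: `post_mean`, `post_sd`, `lfsr`
#'   (genes x conditions), `lfsr_overall`, plus the model (`Ulist`,
#'   `omegas`, `pi`, `C`).
#' @export
posterior_summaries <- function(Bhat, Shat, Ulist, omegas, C, pi, LL = NULL) {
  imp <- .mash_impute(Bhat, Shat)
  if (is.null(LL))
    LL <- .mash_loglik_cpp(imp$Bhat, imp$Shat, C, unname(Ulist), omegas)
  post <- .mash_posterior_cpp(imp$Bhat, imp$Shat, C, unname(Ulist), omegas,
                              pi, LL)
  dn <- dimnames(Bhat)
  pm <- post$post_mean; psd <- post$post_sd; lfsr <- post$lfsr
  dimnames(pm) <- dimnames(psd) <- dimnames(lfsr) <- dn
  pm[imp$missing] <- NA_real_
  psd[imp$missing] <- NA_real_
  lfsr[imp$missing] <- NA_real_
  overall <- apply(lfsr, 1, function(x)
    if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE))
  structure(list(post_mean = pm, post_sd = psd, lfsr = lfsr,
                 lfsr_overall = overall,
                 model = list(Ulist = Ulist, omegas = omegas, pi = pi, C = C)),
            class = "mash_result")
}

#' @export
print.mash_result <- function(x, ...) {
  cat("mash_result:", nrow(x$lfsr), "genes x", ncol(x$lfsr), "conditions; ",
      sum(x$lfsr_overall < 0.05, na.rm = TRUE),
      "genes at overall lfsr < 0.05\n")
  invisible(x)
}

#' One-call multivariate adaptive shrinkage analysis
#'
#' Convenience wrapper: estimates the residual correlation, builds the
#' covariance list and scale grid, fits the mixture weights by EM, and
#' computes posterior summaries.
#'
#' @inheritParams fit_mixture_em
#' @param n_pcs data-driven covariance rank (see
#'   [mash_data_driven_covariances()]).
#' @param C optional residual correlation; estimated when `NULL`.
#' @return a `"mash_result"` (see [posterior_summaries()]) with the fitted
#'   weights in `$model$pi` and the EM trace in `$em`.
#' @export
mash_lite <- function(Bhat, Shat, C = NULL, n_pcs = min(3L, ncol(Bhat)),
                      null_biased = TRUE, tol = 1e-6, max_iter = 1000) {
  stopifnot(identical(dim(Bhat), dim(Shat)))
  if (is.null(C)) C <- estimate_residual_correlation(Bhat, Shat)
  Ulist <- build_covariances(Bhat, Shat, n_pcs = n_pcs)
  omegas <- mash_grid(Bhat, Shat)
  em <- fit_mixture_em(Bhat, Shat, Ulist, omegas, C,
                       null_biased = null_biased, tol = tol,
                       max_iter = max_iter)
  res <- posterior_summaries(Bhat, Shat, Ulist, omegas, C, em$pi, LL = em$LL)
  res$em <- em[c("loglik", "excluded")]
  res
}
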