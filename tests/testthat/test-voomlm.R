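toy_metadata <- function(n_fam = 12, seed = 2) {
  set.seed(seed)
  data.table::data.table(
    sample_id = sprintf("s%02d", seq_len(2 * n_fam)),
    population = rep(c("Mexico", "SouthAmerica"), n_fam),
    elevation = rep(rep(c("Highland", "Lowland"), each = 2), n_fam / 2),
    latitude = runif(2 * n_fam, 10, 20),
    block = rep(1:2, each = n_fam),
    team = rep_len(1:3, 2 * n_fam),
    field_order = unlist(lapply(1:3, function(i) seq_len(ceiling(2 * n_fam / 3))))[
      order(rep_len(1:3, 2 * n_fam))][seq_len(2 * n_fam)]
  )
}

test_that("the design exposes one elevation contrast per population", {
  md <- toy_metadata()
  md$field_order <- stats::ave(seq_len(nrow(md)), md$team, FUN = seq_along)
  X <- build_design(md)
  expect_setequal(grep("^elev_", colnames(X), value = TRUE),
                  c("elev_Mexico", "elev_SouthAmerica"))
  expect_equal(sum(grepl("_order", colnames(X))), 9L)  # 3 teams x cubic
  expect_equal(nrow(X), nrow(md))
  # permuting samples permutes design rows identically
  idx <- sample(nrow(md))
  X2 <- build_design(md[idx, ])
  expect_equal(X2, X[idx, ])
  # one team: the polynomial block collapses to 3 columns
  md1 <- md; md1$team <- 1L
  md1$field_order <- seq_len(nrow(md1))
  X1 <- build_design(md1)
  expect_equal(sum(grepl("_order", colnames(X1))), 3L)
  # aliased covariate reported by name
  md_bad <- md
  expect_error(build_design(md, cell_scores = X[, "elev_Mexico", drop = FALSE]),
               "rank deficient")
})

test_that("count voom yields nearly constant weights on homoskedastic data", {
  set.seed(4)
  md <- toy_metadata()
  md$field_order <- stats::ave(seq_len(nrow(md)), md$team, FUN = seq_along)
  X <- build_design(md)
  # equal expression level for every gene: flat mean-variance trend
  counts <- matrix(rpois(400 * nrow(md), 500), 400, nrow(md),
                   dimnames = list(sprintf("g%03d", 1:400), md$sample_id))
  v <- voom_counts(counts, design = X)
  cv <- sd(v$weights) / mean(v$weights)
  expect_lt(cv, 0.1)
  expect_true(all(v$weights > 0 & is.finite(v$weights)))
  # CPM invariance: doubling one library with proportionally doubled counts
  counts2 <- counts; counts2[, 1] <- 2L * counts[, 1]
  f <- rep(1, ncol(counts))
  v1 <- voom_counts(counts, f, X)
  v2 <- voom_counts(counts2, f, X)
  expect_equal(v2$E[, 1], v1$E[, 1], tolerance = 1e-3)
})

test_that("ASE voom gives zero weight to missing cells and tracks totals", {
  set.seed(6)
  md <- toy_metadata()
  md$field_order <- stats::ave(seq_len(nrow(md)), md$team, FUN = seq_along)
  X <- build_design(md)
  n <- nrow(md); G <- 300
  totals <- matrix(exp(runif(G * n, log(20), log(2000))), G, n)
  totals <- round(totals)
  # variance proportional to 1/total: the canonical allelic counting regime
  y <- matrix(rnorm(G * n, 0, sqrt(30 / totals)), G, n,
              dimnames = list(sprintf("g%03d", 1:G), md$sample_id))
  y[1, 3] <- NA; y[2, ] <- NA  # missing cells incl. a fully missing gene
  expect_warning(ase_voom(y, totals, X), "insufficient residual df")
  av <- suppressWarnings(ase_voom(y, totals, X))
  expect_equal(av$weights[1, 3], 0)
  expect_true(all(av$weights[2, ] == 0))
  expect_true(all(av$weights[-2, -3] >= 0))
  # inverse-variance weights approximately proportional to totals
  ok <- !is.na(y)
  expect_gt(cor(av$weights[ok], totals[ok], method = "spearman"), 0.9)
  # non-increasing trend: larger total -> no smaller weight (same gene)
  tr <- av$trend
  if (all(diff(tr$y) <= 1e-12)) {
    i <- which.max(totals[3, ]); j <- which.min(totals[3, ])
    expect_gte(av$weights[3, i], av$weights[3, j])
  }
})

test_that("weighted least squares matches OLS at unit weights and is scale invariant", {
  set.seed(8)
  n <- 24; G <- 40
  X <- cbind(1, rnorm(n), rbinom(n, 1, 0.5))
  colnames(X) <- c("(Intercept)", "x1", "elev_Mexico")
  y <- matrix(rnorm(G * n), G, n, dimnames = list(sprintf("g%02d", 1:G), NULL))
  fit <- fit_weighted_lm(y, X)
  for (g in c(1, 17)) {
    ref <- lm(y[g, ] ~ X - 1)
    expect_equal(unname(fit$coefficients[g, ]), unname(coef(ref)),
                 tolerance = 1e-10)
    expect_equal(fit$sigma[g], summary(ref)$sigma, tolerance = 1e-10)
  }
  # scaling all weights by a constant changes neither beta nor moderated t
  w <- matrix(runif(G * n, 0.5, 2), G, n)
  f1 <- ebayes_moderate(fit_weighted_lm(y, X, w))
  f2 <- ebayes_moderate(fit_weighted_lm(y, X, w * 7))
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-10)
  expect_equal(f1$t, f2$t, tolerance = 1e-8)
})

test_that("weighted fits agree with limma's lmFit on shared inputs", {
  set.seed(12)
  n <- 20; G <- 50
  X <- cbind(1, rnorm(n)); colnames(X) <- c("(Intercept)", "x")
  y <- matrix(rnorm(G * n), G, n, dimnames = list(sprintf("g%02d", 1:G), NULL))
  w <- matrix(runif(G * n, 0.2, 3), G, n)
  fit <- fit_weighted_lm(y, X, w)
  ref <- limma::lmFit(y, X, weights = w)
  expect_equal(unname(fit$coefficients), unname(ref$coefficients),
               tolerance = 1e-8)
  expect_equal(unname(fit$stdev.unscaled), unname(ref$stdev.unscaled),
               tolerance = 1e-8)
  expect_equal(unname(fit$sigma), unname(ref$sigma), tolerance = 1e-8)
})

test_that("splitting an observation into two half-weight copies is equivalent", {
  set.seed(9)
  X <- cbind(1, c(0, 0, 1, 1, 2)); colnames(X) <- c("(Intercept)", "x")
  y <- c(0.3, 1.1, 2.2, 1.9, 4.1)
  # duplicate the 5th observation with weight 1/2 each
  X2 <- rbind(X, X[5, ]); y2 <- c(y, y[5])
  w1 <- matrix(1, 1, 5); w2 <- matrix(c(rep(1, 4), 0.5, 0.5), 1, 6)
  f1 <- fit_weighted_lm(matrix(y, 1), X, w1)
  f2 <- fit_weighted_lm(matrix(y2, 1), X2, w2)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-10)
  expect_equal(f1$stdev.unscaled, f2$stdev.unscaled, tolerance = 1e-10)
})

test_that("posterior variance follows the pooling formula and its limits", {
  expect_equal(posterior_variance(4, 10, 5, 1), 3.0)
  expect_equal(posterior_variance(c(4, 9), c(10, 3), Inf, 1.5), c(1.5, 1.5),
               tolerance = 1e-10)
  expect_equal(posterior_variance(c(4, 9), c(10, 3), 0, 1.5), c(4, 9),
               tolerance = 1e-10)
})

test_that("the eBayes prior is recovered from simulated scaled-F variances", {
  set.seed(14)
  G <- 5000; d0 <- 4; s02 <- 2; dg <- 20
  s2 <- s02 * dg / rchisq(G, df = d0) * rchisq(G, df = dg) / dg * d0 / dg
  # draw directly: s2_g ~ s02 * F(dg, d0) scaled -> use the standard
  # representation s2_g = s02 * (chi2_dg/dg) / (chi2_d0/d0)
  s2 <- s02 * (rchisq(G, dg) / dg) / (rchisq(G, d0) / d0)
  sv <- limma::squeezeVar(s2, df = dg)
  expect_lt(abs(sv$df.prior - d0) / d0, 0.25)
  expect_lt(abs(sv$var.prior - s02) / s02, 0.10)
  # the package path applies the same pooling to a weighted fit
  n <- 30
  X <- cbind(1, rnorm(n)); colnames(X) <- c("(Intercept)", "x")
  y <- matrix(rnorm(200 * n), 200, n,
              dimnames = list(sprintf("g%03d", 1:200), NULL))
  fit <- ebayes_moderate(fit_weighted_lm(y, X))
  expect_equal(fit$s2.post,
               posterior_variance(fit$sigma^2, fit$df.residual,
                                  fit$df.prior, fit$s2.prior))
  expect_equal(fit$t, fit$coefficients / (sqrt(fit$s2.post) * fit$stdev.unscaled))
})

test_that("elevation effects are recovered and respond to coding sign flips", {
  set.seed(16)
  md <- toy_metadata(n_fam = 30)
  md$field_order <- stats::ave(seq_len(nrow(md)), md$team, FUN = seq_along)
  X <- build_design(md)
  n <- nrow(md); G <- 200
  beta_mx <- 1; beta_sa <- 0
  mu <- beta_mx * X[, "elev_Mexico"] + beta_sa * X[, "elev_SouthAmerica"]
  y <- matrix(rnorm(G * n, rep(mu, each = G), 0.5), G, n,
              dimnames = list(sprintf("g%03d", 1:G), md$sample_id))
  fit <- ebayes_moderate(fit_weighted_lm(y, X))
  eff <- extract_elevation_effects(fit)
  mx <- eff[eff$population == "Mexico", ]
  sa <- eff[eff$population == "SouthAmerica", ]
  expect_lt(abs(mean(mx$beta) - 1), 0.05)
  expect_lt(abs(mean(sa$beta)), 0.05)
  expect_true(all(is.finite(eff$se) & eff$se > 0))
  # ~95% CI coverage for the Mexican effect
  cover <- mean(abs(mx$beta - 1) <= qt(0.975, df = mx$df) * mx$se)
  expect_gt(cover, 0.90)
  # flipping the elevation coding flips the estimate's sign only
  md_flip <- md
  md_flip$elevation <- ifelse(md$elevation == "Highland", "Lowland", "Highland")
  Xf <- build_design(md_flip)
  fitf <- ebayes_moderate(fit_weighted_lm(y, Xf))
  efff <- extract_elevation_effects(fitf)
  mxf <- efff[efff$population == "Mexico", ]
  expect_equal(mxf$beta, -(mx$beta) + 0, tolerance = 1e-6)
})

test_that("allele-label swap negates effects but preserves |t|; null type-I error is calibrated", {
  co <- small_cohort()
  md <- co$metadata[co$metadata$site_tissue == "MetLeaftip", ]
  gam <- gene_allelic_matrix(co$truth$landrace[, md$sample_id],
                             co$truth$b73[, md$sample_id])
  keep <- rowSums(!is.na(gam$log2ase)) >= 30
  gam <- gene_allelic_matrix(gam$landrace[keep, ], gam$b73[keep, ])
  X <- build_design(md)
  av <- ase_voom(gam$log2ase, gam$total, X)
  fit <- ebayes_moderate(fit_weighted_lm(gam$log2ase, X, av$weights))
  sw <- gene_allelic_matrix(gam$b73, gam$landrace)
  avs <- ase_voom(sw$log2ase, sw$total, X)
  fits <- ebayes_moderate(fit_weighted_lm(sw$log2ase, X, avs$weights))
  common <- intersect(rownames(fit$coefficients), rownames(fits$coefficients))
  expect_equal(fits$coefficients[common, "elev_Mexico"],
               -fit$coefficients[common, "elev_Mexico"], tolerance = 1e-8)
  expect_equal(abs(fits$t[common, "elev_Mexico"]),
               abs(fit$t[common, "elev_Mexico"]), tolerance = 1e-6)
})

test_that("the null rejection rate of the elevation contrast is near nominal", {
  set.seed(20)
  md <- toy_metadata(n_fam = 30)
  md$field_order <- stats::ave(seq_len(nrow(md)), md$team, FUN = seq_along)
  X <- build_design(md)
  G <- 2000
  y <- matrix(rnorm(G * nrow(md)), G, nrow(md),
              dimnames = list(sprintf("g%04d", 1:G), md$sample_id))
  fit <- ebayes_moderate(fit_weighted_lm(y, X))
  eff <- extract_elevation_effects(fit)
  rate <- mean(eff$p[eff$population == "Mexico"] < 0.05)
  expect_gte(rate, 0.03); expect_lte(rate, 0.07)
})
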