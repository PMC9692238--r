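test_that("residual correlation is recovered from z-scores", {
  set.seed(3)
  J <- 5000
  z <- matrix(rnorm(J * 4), J, 4)
  C <- estimate_residual_correlation(z, matrix(1, J, 4))
  expect_equal(diag(C), rep(1, 4), tolerance = 1e-8)
  expect_lt(max(abs(C[upper.tri(C)])), 0.05)
  expect_equal(C, t(C))
  # duplicated condition columns show up as near-unit correlation
  z2 <- cbind(z[, 1], z[, 1], z[, 2])
  C2 <- estimate_residual_correlation(z2, matrix(1, J, 3))
  expect_gt(C2[1, 2], 0.9)
  # too few near-null genes: identity with a warning
  expect_warning(C3 <- estimate_residual_correlation(
    matrix(10, 60, 2), matrix(1, 60, 2)), "identity")
  expect_equal(C3, diag(2))
})

test_that("canonical covariances reduce and stay positive semi-definite", {
  u1 <- mash_canonical_covariances(1)
  expect_equal(length(u1), 1L)          # everything collapses to scalar 1
  expect_equal(unname(u1[[1]]), matrix(1, 1, 1))
  u6 <- mash_canonical_covariances(6)
  expect_setequal(names(u6), c("identity", paste0("singleton_", 1:6),
                               "equal_effects", "het_0.25", "het_0.5",
                               "het_0.75"))
  for (U in u6)
    expect_gte(min(eigen(U, symmetric = TRUE)$values), -1e-10)
})

test_that("data-driven covariances capture an equal-effects structure", {
  set.seed(5)
  J <- 2000; R <- 4
  b <- rnorm(J, 0, 3) * (runif(J) < 0.2)
  Bhat <- matrix(rep(b, R), J, R) + matrix(rnorm(J * R, 0, 0.5), J, R)
  dd <- mash_data_driven_covariances(Bhat, matrix(0.5, J, R), n_pcs = 2)
  ones <- matrix(1, R, R) / R
  cosine <- sum(dd$pca_1 * ones) / sqrt(sum(dd$pca_1^2) * sum(ones^2))
  expect_gt(cosine, 0.95)
  for (U in dd)
    expect_gte(min(eigen(U, symmetric = TRUE)$values), -1e-10)
  # too few strong genes: canonical-only with warning
  expect_warning(empty <- mash_data_driven_covariances(
    matrix(0, 50, 4), matrix(1, 50, 4)), "strong")
  expect_equal(length(empty), 0L)
})

test_that("the scale grid spans measurement error to beyond the largest effect", {
  Bhat <- matrix(c(-3, 0.2, 1), 3, 1); Shat <- matrix(0.5, 3, 1)
  g <- mash_grid(Bhat, Shat)
  expect_equal(g[1], (0.5 / 10)^2)
  expect_gte(max(g), (4 * 3)^2 / 2)
  expect_equal(unique(round(diff(log2(g)), 10)), 1)  # ratio 2
})

test_that("posterior summaries reproduce the conjugate closed forms", {
  # R = 1, single covariance, omega = 1, no null: b|Bhat ~ shrinkage by 1/2
  U <- list(scalar = matrix(1, 1, 1))
  Bhat <- matrix(2, 1, 1); Shat <- matrix(1, 1, 1)
  res <- posterior_summaries(Bhat, Shat, U, omegas = 1, C = diag(1),
                             pi = c(0, 1))
  expect_equal(unname(res$post_mean[1, 1]), 1.0)
  expect_equal(unname(res$post_sd[1, 1]), sqrt(1 / 2), tolerance = 1e-10)
  # pure null: posterior mean 0 and lfsr 1 everywhere
  res0 <- posterior_summaries(Bhat, Shat, U, omegas = 1, C = diag(1),
                              pi = c(1, 0))
  expect_equal(unname(res0$post_mean[1, 1]), 0)
  expect_equal(unname(res0$lfsr[1, 1]), 1)
})

test_that("lfsr matches a brute-force quadrature oracle on a 2-condition toy", {
  # mixture: null + identity(omega = 0.5) + het(omega = 1.2); correlated errors
  R <- 2
  U <- list(identity = diag(2),
            het = matrix(c(1, 0.5, 0.5, 1), 2))
  omegas <- c(0.5, 1.2)
  C <- matrix(c(1, 0.3, 0.3, 1), 2)
  pi_vec <- c(0.3, 0.25, 0.1, 0.05, 0.3)  # null, id x 2 omegas, het x 2
  Bhat <- matrix(c(1.4, -0.6), 1, 2)
  Shat <- matrix(c(1, 1.5), 1, 2)
  res <- posterior_summaries(Bhat, Shat, U, omegas, C, pi_vec)
  # oracle: dense grid quadrature over the 2-D effect space
  V <- diag(as.vector(Shat)) %*% C %*% diag(as.vector(Shat))
  dmv <- function(x, S) {
    si <- solve(S)
    exp(-0.5 * rowSums((x %*% si) * x)) / (2 * pi * sqrt(det(S)))
  }
  h <- 0.02
  g <- seq(-8, 8, by = h)
  bgrid <- as.matrix(expand.grid(b1 = g, b2 = g))
  lik <- dmv(sweep(-bgrid, 2, -as.vector(Bhat)), V)
  comps <- list(U[[1]] * omegas[1], U[[1]] * omegas[2],
                U[[2]] * omegas[1], U[[2]] * omegas[2])
  prior <- Reduce(`+`, Map(function(w, S) w * dmv(bgrid, S),
                           as.list(pi_vec[-1]), comps))
  post_unnorm <- prior * lik * h^2
  null_mass <- pi_vec[1] * dmv(matrix(as.vector(Bhat), 1), V)
  Z <- sum(post_unnorm) + null_mass
  for (r in 1:2) {
    zero_line <- sum(post_unnorm[bgrid[, r] == 0])  # split between tails
    p_neg <- (sum(post_unnorm[bgrid[, r] < 0]) + zero_line / 2 + null_mass) / Z
    p_pos <- (sum(post_unnorm[bgrid[, r] > 0]) + zero_line / 2 + null_mass) / Z
    lfsr_oracle <- min(p_neg, p_pos)
    expect_equal(unname(res$lfsr[1, r]), lfsr_oracle, tolerance = 1e-4)
    pm_oracle <- sum(post_unnorm * bgrid[, r]) / Z
    expect_equal(unname(res$post_mean[1, r]), pm_oracle, tolerance = 1e-4)
  }
})

test_that("a pure-null simulation is recognized as null", {
  set.seed(1)
  J <- 5000; R <- 6
  Bhat <- matrix(rnorm(J * R), J, R)
  Shat <- matrix(1, J, R)
  em <- fit_mixture_em(Bhat, Shat, mash_canonical_covariances(R),
                       mash_grid(Bhat, Shat), diag(R))
  expect_equal(sum(em$pi), 1, tolerance = 1e-10)
  # the null component dominates and what little mass escapes it sits on
  # scales that imply a negligible prior effect variance
  expect_gte(em$pi[[1]], 0.5)
  om_of <- as.numeric(sub(".*omega=", "", names(em$pi)[-1]))
  expect_lte(sum(em$pi[-1] * om_of), 0.2)
  # no gene is called significant on null data
  res <- posterior_summaries(Bhat, Shat, mash_canonical_covariances(R),
                             mash_grid(Bhat, Shat), diag(R), em$pi)
  expect_equal(sum(res$lfsr_overall < 0.05), 0L)
  # and reproducible under a fixed gene order
  em2 <- fit_mixture_em(Bhat, Shat, mash_canonical_covariances(R),
                        mash_grid(Bhat, Shat), diag(R))
  expect_identical(em$pi, em2$pi)
})

test_that("a 50/50 null and equal-effects mixture puts half the mass on the equal family", {
  set.seed(2)
  J <- 5000; R <- 6
  Bhat <- matrix(rnorm(J * R), J, R)
  shared <- rnorm(J / 2)
  Bhat[seq_len(J / 2), ] <- Bhat[seq_len(J / 2), ] + shared
  Shat <- matrix(1, J, R)
  em <- fit_mixture_em(Bhat, Shat, mash_canonical_covariances(R),
                       mash_grid(Bhat, Shat), diag(R))
  fam <- vapply(strsplit(names(em$pi), ";"), `[`, "", 1)
  mass <- tapply(em$pi, fam, sum)
  expect_lt(abs(mass[["equal_effects"]] - 0.5), 0.05)
})

test_that("scalar shrinkage never increases the effect magnitude (R = 1)", {
  set.seed(7)
  J <- 300
  Bhat <- matrix(rnorm(J, 0, 2), J, 1)
  Shat <- matrix(runif(J, 0.5, 1.5), J, 1)
  U <- mash_canonical_covariances(1)
  om <- mash_grid(Bhat, Shat)
  em <- fit_mixture_em(Bhat, Shat, U, om, diag(1))
  res <- posterior_summaries(Bhat, Shat, U, om, diag(1), em$pi)
  expect_true(all(abs(res$post_mean) <= abs(Bhat) + 1e-10))
})

test_that("permuting the condition order permutes all outputs consistently", {
  set.seed(9)
  J <- 400; R <- 3
  Bhat <- matrix(rnorm(J * R, 0, 1.5), J, R,
                 dimnames = list(NULL, c("a", "b", "c")))
  Shat <- matrix(runif(J * R, 0.5, 2), J, R, dimnames = dimnames(Bhat))
  Bhat[, 2] <- Bhat[, 2] + rnorm(J, 0, 1)
  perm <- c(3, 1, 2)
  U <- mash_canonical_covariances(R)
  om <- mash_grid(Bhat, Shat)
  em <- fit_mixture_em(Bhat, Shat, U, om, diag(R))
  res <- posterior_summaries(Bhat, Shat, U, om, diag(R), em$pi)
  # permute inputs, keep the same (permuted) covariances and weights
  Up <- lapply(U, function(u) u[perm, perm])
  resp <- posterior_summaries(Bhat[, perm], Shat[, perm], Up, om,
                              diag(R), em$pi)
  expect_equal(unname(resp$post_mean), unname(res$post_mean[, perm]),
               tolerance = 1e-8)
  expect_equal(unname(resp$lfsr), unname(res$lfsr[, perm]), tolerance = 1e-8)
})

test_that("missing conditions are masked in the outputs", {
  set.seed(10)
  J <- 100
  Bhat <- matrix(rnorm(J * 2), J, 2); Bhat[1:10, 2] <- NA
  Shat <- matrix(1, J, 2); Shat[1:10, 2] <- NA
  res <- suppressWarnings(mash_lite(Bhat, Shat, C = diag(2)))
  expect_true(all(is.na(res$post_mean[1:10, 2])))
  expect_true(all(is.na(res$lfsr[1:10, 2])))
  expect_true(all(is.finite(res$lfsr_overall[1:10])))  # min over observed
})

test_that("sign calls at lfsr < 0.05 have a controlled sign-error rate", {
  set.seed(11)
  J <- 3000; R <- 6
  nonzero <- runif(J) < 0.1
  true_b <- matrix(0, J, R)
  true_b[nonzero, ] <- rnorm(sum(nonzero), 0, 1.5)  # shared across conditions
  Shat <- matrix(runif(J * R, 0.3, 1), J, R)
  Bhat <- true_b + matrix(rnorm(J * R), J, R) * Shat
  res <- mash_lite(Bhat, Shat, C = diag(R))
  called <- which(res$lfsr < 0.05, arr.ind = TRUE)
  expect_gt(nrow(called), 200)
  sign_err <- mean(sign(res$post_mean[called]) != sign(true_b[called]))
  expect_lte(sign_err, 0.07)
})
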