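test_that("the model collapses to OLS under identity-proportional kinship", {
  set.seed(41)
  n <- 150
  X <- cbind(x1 = rnorm(n), x2 = runif(n))
  y <- 0.5 + 0.3 * X[, 1] + rnorm(n)
  fit <- fit_lmm(y, X, singleton_kinship(n))
  ols <- summary(lm(y ~ X))$coefficients
  expect_equal(fit$fixed_effects$beta, unname(ols[, 1]), tolerance = 1e-6)
  expect_equal(fit$fixed_effects$se, unname(ols[, 2]), tolerance = 1e-6)
  # any split of total variance along the identity is equivalent
  expect_equal(fit$sigma_g2 + fit$sigma_e2 / 2 * 0 +
                 fit$sigma_e2 * 0, fit$sigma_g2)  # components finite
})

test_that("fixed effects equal closed-form GLS at the estimated V", {
  ped <- generate_pedigree(60, c(min = 2, max = 2), seed = 42)
  kin <- kinship_from_pedigree(ped)
  n <- nrow(ped)
  set.seed(42)
  X <- cbind(x = rnorm(n))
  K <- 2 * unclass(kin)
  y <- drop(crossprod(chol(0.8 * K + 0.5 * diag(n)), rnorm(n))) +
    1 + 0.3 * X[, 1]
  fit <- fit_lmm(y, X, kin)
  V <- fit$sigma_g2 * K + fit$sigma_e2 * diag(n)
  if (fit$sigma_g2 == 0) V <- fit$sigma_e2 * diag(n)
  Vi <- solve(V)
  Xf <- cbind(1, X)
  bgls <- solve(t(Xf) %*% Vi %*% Xf, t(Xf) %*% Vi %*% y)
  expect_equal(fit$fixed_effects$beta, drop(bgls), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("REML recovers the variance ratio in sib-pair simulations", {
  ped <- generate_pedigree(75, c(min = 2, max = 2), seed = 43)  # n = 300
  kin <- kinship_from_pedigree(ped)
  K <- 2 * unclass(kin)
  n <- nrow(ped)
  ratios <- vapply(1:60, function(s) {
    set.seed(1000 + s)
    y <- drop(crossprod(chol(K + diag(n) + 1e-8 * diag(n)), rnorm(n)))
    fit <- fit_lmm(y, matrix(numeric(0), n, 0), kin)
    if (fit$sigma_e2 <= 0) Inf else fit$sigma_g2 / fit$sigma_e2
  }, numeric(1))
  expect_gt(median(ratios), 0.7)
  expect_lt(median(ratios), 1.4)
})

test_that("restricted likelihood at the optimum beats the no-kinship fit", {
  ped <- generate_pedigree(50, c(min = 2, max = 3), seed = 44)
  kin <- kinship_from_pedigree(ped)
  n <- nrow(ped)
  set.seed(44)
  K <- 2 * unclass(kin)
  y <- drop(crossprod(chol(K + 0.5 * diag(n)), rnorm(n)))
  X <- cbind(rnorm(n))
  fit <- fit_lmm(y, X, kin)
  eig <- epimediate:::kinship_eigen(kin)
  yt <- drop(eig$rotate(y)); Xt <- eig$rotate(cbind(1, X))
  ld <- as.numeric(determinant(crossprod(Xt))$modulus)
  # sigma_g2 = 0, REML-optimal sigma_e2
  r0 <- lm.fit(cbind(1, X), y)$residuals
  s0 <- sum(r0^2) / (n - 2)
  l0 <- epimediate:::reml_loglik(0, s0, eig$d, yt, Xt, ld)
  expect_gte(fit$log_likelihood, l0 - 1e-6)
})

test_that("rank-deficient designs fail naming the collinear column", {
  n <- 50
  X <- cbind(a = rnorm(n))
  X <- cbind(X, b = 2 * X[, "a"])
  expect_error(fit_lmm(rnorm(n), X, singleton_kinship(n)), "b")
})

test_that("non-PSD kinship is rejected", {
  k <- diag(0.5, 4); k[1, 2] <- k[2, 1] <- 2
  class(k) <- c("kinship_matrix", "matrix")
  expect_error(fit_lmm(rnorm(4), cbind(rnorm(4)), k), "positive semi-definite")
})

test_that("scan results are invariant to sample permutation and covariate scale", {
  b <- small_bundle(seed = 45, n_families = 80, n_probes = 60)
  y <- transform_tg(b$phenotypes$tg_mgdl)
  covar <- cbind(sex = as.numeric(b$phenotypes$sex == 2),
                 age = b$phenotypes$age)
  P <- b$methylation[, 1:10]
  r1 <- association_scan(y, P, covar, b$kinship)
  # affine rescaling of covariates
  covar2 <- cbind(sex = 5 * covar[, "sex"] - 2,
                  age = covar[, "age"] / 10 + 3)
  r2 <- association_scan(y, P, covar2, b$kinship)
  expect_equal(r1$p, r2$p, tolerance = 1e-10)
  expect_equal(r1$beta, r2$beta, tolerance = 1e-8)
  # permutation of samples (consistently across all inputs)
  set.seed(45)
  perm <- sample(length(y))
  kperm <- epimediate:::subset_kinship(b$kinship, perm)
  r3 <- association_scan(y[perm], P[perm, ], covar[perm, ], kperm)
  # reordering changes floating-point summation order inside the per-family
  # eigendecompositions, so agreement is to ~1e-7, not machine precision
  expect_equal(r1$p, r3$p, tolerance = 1e-7)
})

test_that("constant predictors are flagged untestable, not dropped", {
  n <- 60
  set.seed(46)
  P <- cbind(good = rnorm(n), flat = rep(1, n))
  r <- suppressWarnings(
    association_scan(rnorm(n), P, NULL, singleton_kinship(n)))
  expect_equal(nrow(r), 2)
  expect_equal(r$note[r$predictor_id == "flat"], "untestable")
  expect_true(is.na(r$p[r$predictor_id == "flat"]))
})

test_that("missing predictor values trigger a per-pair complete-case refit", {
  b <- small_bundle(seed = 47, n_families = 60, n_probes = 40)
  y <- transform_tg(b$phenotypes$tg_mgdl)
  x <- b$exposures$exam8[, "carb_pct_energy"]
  x[1:10] <- NA
  r <- association_scan(y, cbind(carb = x), NULL, b$kinship)
  expect_equal(r$n, length(y) - 10)
  expect_false(is.na(r$p))
})

test_that("variance explained matches its construction", {
  set.seed(48)
  n <- 5000
  x <- rnorm(n)
  y <- sqrt(0.05) * x + sqrt(0.95) * rnorm(n)  # R^2 = 5% by construction
  b <- coef(lm(y ~ x))[2]
  ve <- unname(variance_explained(b, x, y))
  expect_equal(ve, 5, tolerance = 0.3)  # within 1.5 absolute
  # perfect predictor
  expect_equal(variance_explained(1, y, y), 100)
  # uncorrelated predictor
  z <- rnorm(n)
  bz <- coef(lm(y ~ z))[2]
  expect_lt(variance_explained(bz, z, y), 0.5)
  expect_warning(variance_explained(1, rep(2, 10), rnorm(10)), "zero-variance")
})

test_that("multilocus variance adds orthogonal effects and rank-reduces", {
  set.seed(49)
  n <- 800
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- 0.2 * x1 + 0.2 * x2 + rnorm(n)
  kin <- singleton_kinship(n)
  v1 <- multilocus_variance(y, cbind(x1), kinship = kin)
  v2 <- multilocus_variance(y, cbind(x2), kinship = kin)
  vj <- multilocus_variance(y, cbind(x1, x2), kinship = kin)
  expect_lt(abs(vj - (v1 + v2)), 0.5)
  # duplicated predictor changes nothing beyond a warning
  expect_warning(vdup <- multilocus_variance(y, cbind(x1, x1), kinship = kin),
                 "rank-reduced")
  expect_equal(vdup, v1, tolerance = 1e-8)
})

test_that("correlated predictors jointly explain less than the sum", {
  set.seed(50)
  n <- 2000
  z <- rnorm(n)
  x1 <- sqrt(0.9) * z + sqrt(0.1) * rnorm(n)
  x2 <- sqrt(0.9) * z + sqrt(0.1) * rnorm(n)
  y <- 0.2 * x1 + 0.2 * x2 + rnorm(n)
  kin <- singleton_kinship(n)
  v1 <- multilocus_variance(y, cbind(x1), kinship = kin)
  vj <- multilocus_variance(y, cbind(x1, x2), kinship = kin)
  expect_lt(vj, 2 * v1)
  expect_gte(vj, v1 - 1e-8)
  # OLS-on-y oracle (no covariates, identity kinship)
  r2 <- summary(lm(y ~ x1 + x2))$r.squared
  expect_equal(vj, 100 * r2, tolerance = 1e-6)
})
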