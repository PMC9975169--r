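# ---- kinship eigendecomposition -------------------------------------------
# The genetic covariance is 2*Phi*sigma_g2. Family-based kinship matrices
# are block-diagonal, so K = 2*Phi is eigendecomposed per family block
# (O(sum n_f^3) instead of O(n^3)); the rotation U' m is applied block-wise.

kinship_eigen <- function(kin) {
  K <- 2 * unclass(kin)
  n <- nrow(K)
  fam <- attr(kin, "family")
  blocks <- if (!is.null(fam) && length(fam) == n) split(seq_len(n), fam)
            else list(seq_len(n))
  eigs <- lapply(blocks, function(rows) {
    e <- eigen(K[rows, rows, drop = FALSE], symmetric = TRUE)
    list(rows = rows, U = e$vectors, d = e$values)
  })
  d <- unlist(lapply(eigs, `[[`, "d"), use.names = FALSE)
  if (min(d) < -1e-8) stop("kinship matrix is not positive semi-definite")
  perm <- unlist(lapply(eigs, `[[`, "rows"), use.names = FALSE)
  rotate <- function(m) {
    m <- as.matrix(m)
    out <- matrix(0, nrow(m), ncol(m))
    i <- 1L
    for (b in eigs) {
      k <- length(b$rows)
      out[i:(i + k - 1L), ] <- crossprod(b$U, m[b$rows, , drop = FALSE])
      i <- i + k
    }
    out
  }
  list(d = pmax(d, 0), rotate = rotate, perm = perm, n = n)
}

# restricted log-likelihood at given variance components, in rotated space
reml_loglik <- function(sg2, se2, d, yt, Xt, logdet_XtX) {
  v <- sg2 * d + se2
  if (any(v <= 0)) return(-Inf)
  w <- 1 / v
  A <- crossprod(Xt, w * Xt)
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  beta <- backsolve(ch, forwardsolve(t(ch), crossprod(Xt, w * yt)))
  r <- yt - Xt %*% beta
  rss <- sum(w * r^2)
  p <- ncol(Xt)
  n <- length(yt)
  -0.5 * (sum(log(v)) + 2 * sum(log(diag(ch))) - logdet_XtX +
            rss + (n - p) * log(2 * pi))
}

#' Fit a kinship linear mixed model by REML
#'
#' Model: y = X b + g + e with cov(g) = 2 Phi sigma_g2 and cov(e) =
#' I sigma_e2. The restricted likelihood is profiled over the ratio
#' delta = sigma_e2 / sigma_g2 after a single eigendecomposition of 2 Phi
#' (done per family block when the matrix is block-diagonal). Fixed effects
#' are estimated by GLS at the optimum; Wald two-sided p-values use the
#' t distribution with residual degrees of freedom. Samples with any
#' missing value in y or X are dropped (complete-case).
#'
#' @param y response vector (names = sample ids, optional)
#' @param X covariate/design matrix including the intercept column if
#'   desired; a column named `(Intercept)` is added when absent
#' @param kinship kinship matrix Phi over the same samples
#' @return object of class `lmm_fit`: `fixed_effects` (data.frame with
#'   beta, se, z, p per column of X), `sigma_g2`, `sigma_e2`, `n_used`,
#'   `log_likelihood` (restricted), `df_residual`
#' @export
fit_lmm <- function(y, X, kinship) {
  X <- as.matrix(X)
  if (ncol(X) > 0 && is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (!"(Intercept)" %in% colnames(X))
    X <- cbind(`(Intercept)` = rep(1, length(y)), X)
  keep <- complete.cases(y, X)
  y <- y[keep]; X <- X[keep, , drop = FALSE]
  kin <- subset_kinship(kinship, keep)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(drop_cols, collapse = ", "))
  }
  eig <- kinship_eigen(kin)
  yt <- drop(eig$rotate(y))
  Xt <- eig$rotate(X)
  logdet_XtX <- as.numeric(determinant(crossprod(Xt), logarithm = TRUE)$modulus)

  obj <- function(logdelta) {
    # profile: sg2 free scale at fixed ratio; optimize scale analytically
    delta <- exp(logdelta)
    v <- eig$d + delta
    w <- 1 / v
    A <- crossprod(Xt, w * Xt)
    ch <- chol(A)
    beta <- backsolve(ch, forwardsolve(t(ch), crossprod(Xt, w * yt)))
    r <- yt - Xt %*% beta
    rss <- sum(w * r^2)
    n <- length(yt); p <- ncol(Xt)
    sg2 <- rss / (n - p)
    -0.5 * ((n - p) * (log(2 * pi * sg2) + 1) + sum(log(v)) +
              2 * sum(log(diag(ch))) - logdet_XtX + (n - p) * log(1))
  }
  grid <- seq(-10, 10, length.out = 21)
  vals <- vapply(grid, obj, numeric(1))
  i <- which.max(vals)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- optimize(obj, c(lo, hi), maximum = TRUE, tol = 1e-11)
  delta <- exp(opt$maximum)

  v <- eig$d + delta
  w <- 1 / v
  A <- crossprod(Xt, w * Xt)
  Ainv <- chol2inv(chol(A))
  beta <- drop(Ainv %*% crossprod(Xt, w * yt))
  r <- yt - Xt %*% beta
  n <- length(yt); p <- ncol(Xt)
  scale <- sum(w * r^2) / (n - p)
  sg2 <- scale
  se2 <- scale * delta
  # near-boundary ratio: report a zero genetic component, all noise residual
  if (delta > exp(9.5)) { se2 <- scale * (1 + delta) - scale; sg2 <- 0 }
  se <- sqrt(diag(Ainv) * scale)
  z <- beta / se
  # Wald t with residual df: exact OLS equivalence when kinship is
  # identity-proportional; indistinguishable from normal at cohort scale
  pval <- 2 * stats::pt(-abs(z), df = n - p)
  ll <- reml_loglik(sg2, se2, eig$d, yt, Xt, logdet_XtX)
  structure(list(
    fixed_effects = data.frame(term = colnames(X), beta = beta, se = se,
                               z = z, p = pval, row.names = NULL),
    sigma_g2 = sg2, sigma_e2 = se2, delta = delta,
    n_used = n, df_residual = n - p, log_likelihood = ll,
    eig = eig, yt = yt, Xt = Xt, logdet_XtX = logdet_XtX),
    class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("kinship LMM fit: n = %d, sigma_g2 = %.4g, sigma_e2 = %.4g\n",
              x$n_used, x$sigma_g2, x$sigma_e2))
  print(x$fixed_effects, digits = 4)
  invisible(x)
}

subset_kinship <- function(kin, keep) {
  fam <- attr(kin, "family")
  k <- unclass(kin)[keep, keep, drop = FALSE]
  if (!is.null(fam)) attr(k, "family") <- fam[keep]
  class(k) <- c("kinship_matrix", "matrix")
  k
}

#' Partial variance explained by one fixed effect
#'
#' Defined as `100 * beta_hat^2 * var(x) / var(y_adj)` where `y_adj` is the
#' response residualized on all other fixed effects; clamped to [0, 100].
#'
#' @param beta_hat estimated coefficient of the predictor
#' @param x predictor values (complete cases used in the fit)
#' @param y_adj response adjusted for the other fixed effects
#' @return percent in [0, 100]; 0 with a warning for a zero-variance
#'   predictor
#' @export
variance_explained <- function(beta_hat, x, y_adj) {
  vx <- var(x)
  if (!is.finite(vx) || vx == 0) {
    warning("zero-variance predictor; variance explained set to 0")
    return(0)
  }
  clamp(100 * beta_hat^2 * vx / var(y_adj), 0, 100)
}

# ---- association scan ------------------------------------------------------

#' Mixed-model association scan of many predictors against one response
#'
#' Variance components are estimated once by REML on the covariate-only
#' null model; each predictor is then tested by GLS with those weights
#' (one eigendecomposition + O(P) solves). Predictors containing missing
#' values fall back to a full per-pair REML fit on the pair's complete
#' cases. Constant predictors are flagged untestable rather than dropped.
#'
#' @param y response vector
#' @param predictors n x P matrix of predictors (tested one at a time)
#' @param covariates n x q covariate matrix (no intercept; added inside)
#' @param kinship kinship matrix over the same samples
#' @param response_id,exam,analysis_set labels copied into the result rows
#' @return data.frame of class `association_result`: response_id,
#'   predictor_id, exam, analysis_set, beta, se, p,
#'   variance_explained_pct, n, note
#' @export
association_scan <- function(y, predictors, covariates = NULL, kinship,
                             response_id = "y", exam = NA_character_,
                             analysis_set = NA_character_) {
  predictors <- as.matrix(predictors)
  if (is.null(colnames(predictors)))
    colnames(predictors) <- paste0("p", seq_len(ncol(predictors)))
  n0 <- length(y)
  X0 <- cbind(`(Intercept)` = rep(1, n0))
  if (!is.null(covariates)) {
    # standardize covariate columns: same column space, and results become
    # numerically invariant under affine covariate rescaling
    cv <- as.matrix(covariates)
    cv <- apply(cv, 2, function(x) {
      s <- sd(x, na.rm = TRUE)
      if (is.finite(s) && s > 0) (x - mean(x, na.rm = TRUE)) / s else x
    })
    X0 <- cbind(X0, cv)
  }
  base_keep <- complete.cases(y, X0)

  yb <- y[base_keep]; Xb <- X0[base_keep, , drop = FALSE]
  kinb <- subset_kinship(kinship, base_keep)
  null_fit <- fit_lmm(yb, Xb, kinb)
  eig <- null_fit$eig
  w <- 1 / (eig$d + null_fit$delta)
  yt <- null_fit$yt
  Xt <- null_fit$Xt

  res <- vector("list", ncol(predictors))
  # covariate-adjusted response for the variance-explained denominator
  y_adj <- stats::lm.fit(Xb, yb)$residuals
  for (j in seq_len(ncol(predictors))) {
    xj <- predictors[base_keep, j]
    note <- ""
    if (anyNA(xj)) {
      ok <- !is.na(xj)
      if (sum(ok) <= ncol(Xb) + 1) {
        res[[j]] <- scan_row(response_id, colnames(predictors)[j], exam,
                             analysis_set, NA, NA, NA, NA, sum(ok),
                             "insufficient_n")
        next
      }
      fitj <- fit_lmm(yb[ok], cbind(Xb[ok, , drop = FALSE], x = xj[ok]),
                      subset_kinship(kinb, ok))
      k <- nrow(fitj$fixed_effects)
      bj <- fitj$fixed_effects$beta[k]; sej <- fitj$fixed_effects$se[k]
      pj <- fitj$fixed_effects$p[k]
      yaj <- stats::lm.fit(Xb[ok, , drop = FALSE], yb[ok])$residuals
      ve <- variance_explained(bj, xj[ok], yaj)
      res[[j]] <- scan_row(response_id, colnames(predictors)[j], exam,
                           analysis_set, bj, sej, pj, ve, sum(ok), "")
      next
    }
    if (var(xj) == 0) {
      res[[j]] <- scan_row(response_id, colnames(predictors)[j], exam,
                           analysis_set, NA, NA, NA, NA, length(xj),
                           "untestable")
      next
    }
    xt <- drop(eig$rotate(xj))
    Xa <- cbind(Xt, xt)
    A <- crossprod(Xa, w * Xa)
    ch <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(ch)) {
      res[[j]] <- scan_row(response_id, colnames(predictors)[j], exam,
                           analysis_set, NA, NA, NA, NA, length(xj),
                           "collinear")
      next
    }
    Ainv <- chol2inv(ch)
    bet <- drop(Ainv %*% crossprod(Xa, w * yt))
    r <- yt - Xa %*% bet
    s2 <- sum(w * r^2) / (length(yt) - ncol(Xa))
    k <- ncol(Xa)
    bj <- bet[k]; sej <- sqrt(Ainv[k, k] * s2)
    pj <- 2 * stats::pt(-abs(bj / sej), df = length(yt) - ncol(Xa))
    ve <- variance_explained(bj, xj, y_adj)
    res[[j]] <- scan_row(response_id, colnames(predictors)[j], exam,
                         analysis_set, bj, sej, pj, ve, length(xj), "")
  }
  out <- do.call(rbind, res)
  class(out) <- c("association_result", "data.frame")
  out
}

scan_row <- function(rid, pid, exam, aset, beta, se, p, ve, n, note) {
  data.frame(response_id = rid, predictor_id = pid, exam = exam,
             analysis_set = aset, beta = beta, se = se, p = p,
             variance_explained_pct = ve, n = n, note = note,
             stringsAsFactors = FALSE)
}

#' Joint variance in a response explained by multiple predictors
#'
#' Fits all predictors jointly as fixed effects after projecting out the
#' covariates, under the GLS weights of the covariate-only REML null model;
#' returns `100 * R^2` of the covariate-adjusted response. Collinear
#' predictor sets are rank-reduced with a warning.
#'
#' @param y response vector
#' @param predictors n x m predictor matrix
#' @param covariates optional covariate matrix
#' @param kinship kinship matrix
#' @return percent of covariate-adjusted variance explained jointly
#' @export
multilocus_variance <- function(y, predictors, covariates = NULL, kinship) {
  predictors <- as.matrix(predictors)
  n0 <- length(y)
  X0 <- cbind(`(Intercept)` = rep(1, n0))
  if (!is.null(covariates)) X0 <- cbind(X0, as.matrix(covariates))
  keep <- complete.cases(y, X0, predictors)
  y <- y[keep]; X0 <- X0[keep, , drop = FALSE]
  predictors <- predictors[keep, , drop = FALSE]
  fit0 <- fit_lmm(y, X0, subset_kinship(kinship, keep))
  w <- 1 / (fit0$eig$d + fit0$delta)
  yt <- fit0$yt; Xt <- fit0$Xt
  Pt <- fit0$eig$rotate(predictors)
  sw <- sqrt(w)
  # project covariates out (weighted), then R^2 of adjusted response
  qx <- qr(sw * Xt)
  ya <- qr.resid(qx, sw * yt)
  Pa <- qr.resid(qx, sw * Pt)
  qp <- qr(Pa)
  if (qp$rank < ncol(Pa))
    warning("predictors are collinear after adjustment; rank-reduced from ",
            ncol(Pa), " to ", qp$rank)
  fitted <- qr.fitted(qp, ya)
  100 * sum(fitted^2) / sum(ya^2)
}
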