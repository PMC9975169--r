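#' Specify a single mediation analysis
#'
#' @param exposure exposure variable: a column of the exposure panel, or
#'   "alcohol_pct_energy" (alcohol g/day converted to percent energy with
#'   the Atwater factor)
#' @param mediator CpG probe id (beta value at the reference exam)
#' @param outcome outcome variable (default "log10_tg", computed from the
#'   stored TG mg/dL)
#' @param covariates phenotype covariate columns; cell-type PCs and
#'   hypertension/diabetes medication flags are always added
#' @param extra_adjustment optional second exposure added as a covariate
#'   (mutual adjustment)
#' @param interaction include the exposure x mediator interaction term
#' @param contrast exposure contrast `c(a_star, a)`; default is subset mean
#'   and mean + 1 SD
#' @param exam exam label at which the exposure is taken (default:
#'   reference exam)
#' @return a `mediation_spec` list
#' @export
mediation_spec <- function(exposure, mediator, outcome = "log10_tg",
                           covariates = c("sex", "age", "bmi",
                                          "phys_activity", "smoking_cig_d"),
                           extra_adjustment = NULL, interaction = FALSE,
                           contrast = NULL, exam = NULL) {
  if (identical(exposure, mediator)) stop("exposure and mediator must differ")
  if (!is.null(contrast)) {
    stopifnot(length(contrast) == 2)
    if (contrast[1] == contrast[2]) stop("contrast values must differ")
  }
  structure(list(exposure = exposure, mediator = mediator, outcome = outcome,
                 covariates = covariates, extra_adjustment = extra_adjustment,
                 interaction = interaction, contrast = contrast, exam = exam),
            class = "mediation_spec")
}

# resolve an exposure column at an exam, supporting energy normalization
get_exposure <- function(bundle, var, exam) {
  expo <- bundle$exposures[[exam]]
  if (is.null(expo)) stop("unknown exam: ", exam)
  if (var %in% colnames(expo)) return(expo[, var])
  if (var == "alcohol_pct_energy")
    return(normalize_to_energy(expo[, "alcohol_g_d"], "alcohol",
                               expo[, "total_energy_kcal"]))
  stop("unknown exposure variable: ", var)
}

# assemble the complete-case analysis frame for one mediation spec
mediation_frame <- function(bundle, spec) {
  exam <- spec$exam %||% reference_exam(bundle)
  A <- get_exposure(bundle, spec$exposure, exam)
  if (!spec$mediator %in% colnames(bundle$methylation))
    stop("mediator probe not found: ", spec$mediator)
  M <- bundle$methylation[, spec$mediator]
  Y <- if (spec$outcome == "log10_tg")
    transform_tg(bundle$phenotypes$tg_mgdl) else bundle$phenotypes[[spec$outcome]]
  C <- build_covariates(bundle, spec$covariates, "NoLipidMed")
  if (!is.null(spec$extra_adjustment)) {
    ref <- reference_exam(bundle)
    C <- cbind(C, extra = get_exposure(bundle, spec$extra_adjustment, exam))
    colnames(C)[ncol(C)] <- spec$extra_adjustment
  }
  # mediation runs only in participants not taking lipid-lowering drugs
  sel <- bundle$phenotypes$lipid_med == 0
  keep <- sel & complete.cases(A, M, Y, C)
  if (sum(keep) < 30) stop("fewer than 30 complete cases in subset")
  A <- A[keep]
  if (var(A) == 0) stop("zero exposure variance in analysis subset")
  list(A = A, M = M[keep], Y = Y[keep], C = C[keep, , drop = FALSE],
       fam = bundle$phenotypes$fam[keep], exam = exam)
}

# point estimation on prepared vectors; regression-based counterfactual
# decomposition for continuous exposure, mediator and outcome:
#   mediator model  M = a0 + a1 A + a2' C
#   outcome model   Y = t0 + t1 A + t2 M + t3 A M + t4' C
#   NDE = (t1 + t3 (a0 + a1 a* + a2' c_ref)) (a - a*)
#   NIE = (t2 a1 + t3 a1 a) (a - a*),  TE = NDE + NIE
med_point <- function(A, M, Y, C, interaction, a, a_star, c_ref) {
  Xm <- cbind(1, A, C)
  fm <- stats::.lm.fit(Xm, M)
  am <- fm$coefficients
  alpha0 <- am[1]; alpha1 <- am[2]; alpha2 <- am[-(1:2)]
  Xy <- if (interaction) cbind(1, A, M, A * M, C) else cbind(1, A, M, C)
  fy <- stats::.lm.fit(Xy, Y)
  ty <- fy$coefficients
  theta1 <- ty[2]; theta2 <- ty[3]
  theta3 <- if (interaction) ty[4] else 0
  nde <- (theta1 + theta3 * (alpha0 + alpha1 * a_star +
                               drop(crossprod(alpha2, c_ref)))) * (a - a_star)
  nie <- (theta2 * alpha1 + theta3 * alpha1 * a) * (a - a_star)
  c(te = nde + nie, nde = nde, nie = nie,
    alpha0 = alpha0, alpha1 = alpha1,
    theta1 = theta1, theta2 = theta2, theta3 = theta3)
}

#' Counterfactual mediation point estimates
#'
#' Regression-based natural effect decomposition of the exposure effect on
#' log10 TG through a single CpG mediator, in participants not taking
#' lipid-lowering medication. `TE = NDE + NIE` holds identically; with the
#' interaction off, `NIE` equals the product of coefficients
#' `alpha1 * theta2 * (a - a_star)`.
#'
#' @param bundle a `cohort_bundle` with cell PCs
#' @param spec a [mediation_spec()]
#' @return list of class `mediation_result`: `te`, `nde`, `nie`,
#'   `proportion_mediated_pct` (NA when NIE and TE disagree in sign),
#'   coefficient estimates, `contrast`, `n`, `exam`
#' @export
estimate_mediation <- function(bundle, spec) {
  fr <- mediation_frame(bundle, spec)
  ct <- spec$contrast %||% c(mean(fr$A), mean(fr$A) + sd(fr$A))
  c_ref <- colMeans(fr$C)
  est <- med_point(fr$A, fr$M, fr$Y, fr$C, spec$interaction,
                   a = ct[2], a_star = ct[1], c_ref = c_ref)
  pm <- if (is.finite(est["te"]) && est["te"] != 0 &&
            sign(est["nie"]) == sign(est["te"]))
    100 * est["nie"] / est["te"] else NA_real_
  structure(list(te = unname(est["te"]), nde = unname(est["nde"]),
                 nie = unname(est["nie"]),
                 proportion_mediated_pct = unname(pm),
                 coefficients = est[-(1:3)],
                 contrast = c(a_star = ct[1], a = ct[2]),
                 c_ref = c_ref,
                 exposure = spec$exposure, mediator = spec$mediator,
                 interaction = spec$interaction,
                 n = length(fr$A), exam = fr$exam),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("mediation %s -> %s -> log10 TG (exam %s, n = %d)\n",
              x$exposure, x$mediator, x$exam, x$n))
  cat(sprintf("  TE = %.5f  NDE = %.5f  NIE = %.5f\n", x$te, x$nde, x$nie))
  if (!is.null(x$ci_nie))
    cat(sprintf("  NIE 95%% CI [%.5f, %.5f], bootstrap p = %.4g (B = %d)\n",
                x$ci_nie[1], x$ci_nie[2], x$p_nie, x$n_boot))
  invisible(x)
}

#' Family-clustered bootstrap confidence intervals for mediation
#'
#' Families are resampled with replacement as whole clusters; percentile
#' 95% intervals and two-sided bootstrap p-values (smallest alpha at which
#' the (1 - alpha) percentile interval excludes 0) are attached to the
#' point-estimate result. The exposure contrast and covariate reference of
#' the point estimate are held fixed across replicates.
#'
#' @param bundle a `cohort_bundle`
#' @param spec a [mediation_spec()]
#' @param n_boot bootstrap replicates (>= 100 for reported CIs)
#' @param seed integer seed (mandatory: results must be reproducible)
#' @return `mediation_result` with `ci_te`, `ci_nde`, `ci_nie`, `p_te`,
#'   `p_nde`, `p_nie`, `n_boot`, `seed`
#' @export
bootstrap_mediation <- function(bundle, spec, n_boot = 1000, seed) {
  if (missing(seed)) stop("seed is required")
  if (n_boot < 100) warning("n_boot < 100: intervals will be unstable")
  res <- estimate_mediation(bundle, spec)
  fr <- mediation_frame(bundle, spec)
  fams <- unique(fr$fam)
  if (length(fams) < 10) stop("fewer than 10 family clusters; bootstrap invalid")
  fam_rows <- split(seq_along(fr$fam), fr$fam)[fams]
  a <- res$contrast["a"]; a_star <- res$contrast["a_star"]
  c_ref <- res$c_ref
  set.seed(as.integer(seed))
  boot <- matrix(NA_real_, n_boot, 3,
                 dimnames = list(NULL, c("te", "nde", "nie")))
  for (b in seq_len(n_boot)) {
    idx <- unlist(fam_rows[sample.int(length(fams), replace = TRUE)],
                  use.names = FALSE)
    est <- tryCatch(
      med_point(fr$A[idx], fr$M[idx], fr$Y[idx], fr$C[idx, , drop = FALSE],
                spec$interaction, a, a_star, c_ref),
      error = function(e) rep(NA_real_, 8))
    boot[b, ] <- est[1:3]
  }
  boot_p <- function(v) {
    v <- v[is.finite(v)]
    if (!length(v)) return(NA_real_)
    min(1, 2 * min(mean(v <= 0), mean(v >= 0)))
  }
  qs <- apply(boot, 2, quantile, probs = c(0.025, 0.975), na.rm = TRUE,
              type = 7)
  res$ci_te <- unname(qs[, "te"]); res$ci_nde <- unname(qs[, "nde"])
  res$ci_nie <- unname(qs[, "nie"])
  res$p_te <- boot_p(boot[, "te"]); res$p_nde <- boot_p(boot[, "nde"])
  res$p_nie <- boot_p(boot[, "nie"])
  res$n_boot <- n_boot; res$seed <- as.integer(seed)
  res$boot <- boot
  res
}

#' Wald test of the exposure x mediator interaction
#'
#' @param bundle a `cohort_bundle`
#' @param spec a [mediation_spec()] (interaction is forced on)
#' @return two-sided p-value for the interaction coefficient; NA with
#'   attribute `note = "untestable"` when the mediator is constant
#' @export
interaction_test <- function(bundle, spec) {
  fr <- mediation_frame(bundle, spec)
  if (var(fr$M) == 0)
    return(structure(NA_real_, note = "untestable"))
  Xy <- cbind(`(Intercept)` = 1, A = fr$A, M = fr$M, AM = fr$A * fr$M, fr$C)
  fit <- lm(fr$Y ~ Xy - 1)
  sm <- summary(fit)$coefficients
  i <- grep("AM$", rownames(sm))
  unname(sm[i, 4])
}

#' Run mediation over a grid of exposures, mediators, and exams
#'
#' Each exposure gets its own Bonferroni threshold `alpha / n_mediators`
#' on the bootstrap NIE p-value. Options: `mutual_adjustment` maps each
#' exposure to the variable adjusted for (e.g. alcohol runs adjusted for
#' carbohydrate and vice versa); exposures may be drink-type columns
#' (servings/week).
#'
#' @param bundle a `cohort_bundle`
#' @param exposures character vector of exposure variables
#' @param mediators character vector of probe ids
#' @param exams exam labels (default: reference exam only)
#' @param n_boot bootstrap replicates per cell
#' @param seed integer seed
#' @param alpha family-wise rate per exposure (default 0.05)
#' @param mutual_adjustment optional named character vector: for each
#'   exposure, the other exposure to adjust for
#' @return data.frame with one row per (exposure, mediator, exam):
#'   estimates, CIs, p-values, `threshold`, `significant`
#' @export
mediation_grid <- function(bundle, exposures, mediators, exams = NULL,
                           n_boot = 200, seed = 1, alpha = 0.05,
                           mutual_adjustment = NULL) {
  exams <- exams %||% reference_exam(bundle)
  avail <- colnames(bundle$exposures[[reference_exam(bundle)]])
  bad <- setdiff(setdiff(exposures, "alcohol_pct_energy"), avail)
  if (length(bad)) stop("unknown exposure column(s): ",
                        paste(bad, collapse = ", "))
  rows <- list()
  for (expo in exposures) {
    thr <- bonferroni_threshold(alpha, length(mediators))
    adj <- if (!is.null(mutual_adjustment) && expo %in% names(mutual_adjustment))
      mutual_adjustment[[expo]] else NULL
    for (ex in exams) for (m in mediators) {
      spec <- mediation_spec(expo, m, exam = ex, extra_adjustment = adj)
      cell_seed <- as.integer(seed) +
        37L * (match(m, mediators) + 1000L * match(ex, exams) +
                 100000L * match(expo, exposures))
      r <- bootstrap_mediation(bundle, spec, n_boot = n_boot,
                               seed = cell_seed %% .Machine$integer.max)
      p_int <- interaction_test(bundle, spec)
      rows[[length(rows) + 1L]] <- data.frame(
        exposure = expo, mediator = m, exam = ex,
        adjusted_for = adj %||% "", te = r$te, nde = r$nde, nie = r$nie,
        nie_lo = r$ci_nie[1], nie_hi = r$ci_nie[2],
        nde_lo = r$ci_nde[1], nde_hi = r$ci_nde[2],
        p_te = r$p_te, p_nde = r$p_nde, p_nie = r$p_nie,
        p_interaction = p_int,
        proportion_mediated_pct = r$proportion_mediated_pct,
        n = r$n, n_boot = r$n_boot,
        threshold = as.numeric(thr),
        significant = is.finite(r$p_nie) & r$p_nie <= as.numeric(thr),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
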