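#' Bonferroni significance threshold
#'
#' @param alpha family-wise error rate in (0,1)
#' @param n_tests number of (effective) tests, >= 1
#' @return alpha / n_tests; the value rounded to 4 decimal places is
#'   attached as attribute `display` (the reporting convention used for
#'   thresholds like 0.0003 = 0.05/170 and 0.0045 = 0.05/11)
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)")
  if (n_tests < 1) stop("n_tests must be >= 1")
  thr <- alpha / n_tests
  attr(thr, "display") <- round(thr, 4)
  thr
}

#' Effective number of independent tests (eigenvalue method)
#'
#' Li & Ji (2005) estimator on the eigenvalues of the variable correlation
#' matrix: each eigenvalue contributes `1(lambda >= 1) + (lambda -
#' floor(lambda))`. Correlations are pairwise-complete; eigenvalues that
#' come out slightly negative from pairwise completion are clipped at zero.
#' Zero-variance variables are excluded with a warning. The simpler
#' Cheverud/Nyholt variant (`M * (1 - (M - 1) * var(lambda) / M^2)`) is
#' available for sensitivity analysis.
#'
#' @param exposure_matrix samples x M numeric matrix of exposure variables
#' @param method "liji" (default) or "cheverud"
#' @return list of class `meff_estimate`: `meff`, `n_variables`,
#'   `eigenvalues`, `method`
#' @export
effective_tests <- function(exposure_matrix, method = c("liji", "cheverud")) {
  method <- match.arg(method)
  X <- as.matrix(exposure_matrix)
  vv <- apply(X, 2, function(x) var(x, na.rm = TRUE))
  drop_cols <- !is.finite(vv) | vv == 0
  if (any(drop_cols)) {
    warning(sum(drop_cols), " zero-variance variable(s) excluded from Meff")
    X <- X[, !drop_cols, drop = FALSE]
  }
  M <- ncol(X)
  if (M == 0) stop("no variables left after exclusions")
  if (M == 1) {
    out <- list(meff = 1, n_variables = 1L, eigenvalues = 1, method = method)
    class(out) <- "meff_estimate"
    return(out)
  }
  C <- cor(X, use = "pairwise.complete.obs")
  C[is.na(C)] <- 0; diag(C) <- 1
  lambda <- pmax(eigen(C, symmetric = TRUE, only.values = TRUE)$values, 0)
  # zap float fuzz before the floor(): an eigenvalue that is an integer up
  # to rounding error must not fall to the next lower floor
  lambda <- round(lambda, 9)
  meff <- switch(method,
    liji = sum(as.numeric(lambda >= 1) + (lambda - floor(lambda))),
    cheverud = M * (1 - (M - 1) * var(lambda) / M^2))
  out <- list(meff = min(max(meff, 1), M), n_variables = M,
              eigenvalues = lambda, method = method)
  class(out) <- "meff_estimate"
  out
}

#' Epigenome-wide association scan for log10 TG
#'
#' Scans every retained probe as a predictor of log10 TG in the kinship
#' mixed model. Analysis set "All" keeps everyone and adds the
#' lipid-lowering medication flag as a covariate; "NoLipidMed" restricts to
#' participants not on lipid-lowering medication. Cell-type PCs must be
#' supplied (or precomputed on the bundle with [add_cell_pcs()]).
#'
#' @param bundle a `cohort_bundle`
#' @param covariates character vector of phenotype covariate columns
#'   (default sex, age, and cell-type PCs; add "bmi" to match analyses that
#'   adjust for it)
#' @param analysis_set "All" or "NoLipidMed"
#' @param threshold epigenome-wide significance threshold on p
#' @param probes optional subset of probe ids to scan
#' @return list of class `ewas_summary`: `results` (ordered by p),
#'   `significance_threshold`, `significant_probes`, `analysis_set`, `n`
#' @export
run_ewas <- function(bundle, covariates = c("sex", "age"),
                     analysis_set = c("All", "NoLipidMed"),
                     threshold = 1.1e-7, probes = NULL) {
  analysis_set <- match.arg(analysis_set)
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0,1)")
  sel <- analysis_subset(bundle, analysis_set)
  covar <- build_covariates(bundle, covariates, analysis_set)
  y <- transform_tg(bundle$phenotypes$tg_mgdl)
  P <- bundle$methylation
  if (!is.null(probes)) P <- P[, probes, drop = FALSE]
  res <- association_scan(y[sel], P[sel, , drop = FALSE],
                          covar[sel, , drop = FALSE],
                          subset_kinship(bundle$kinship, sel),
                          response_id = "log10_tg",
                          exam = reference_exam(bundle),
                          analysis_set = analysis_set)
  res <- res[order(res$p), ]
  rownames(res) <- NULL
  sig <- res$predictor_id[!is.na(res$p) & res$p <= threshold]
  structure(list(results = res, significance_threshold = threshold,
                 significant_probes = sig, analysis_set = analysis_set,
                 n = sum(sel)),
            class = "ewas_summary")
}

reference_exam <- function(bundle) {
  ex <- attr(bundle$exposures, "exams")
  ex[length(ex)]
}

analysis_subset <- function(bundle, analysis_set) {
  if (analysis_set == "NoLipidMed") bundle$phenotypes$lipid_med == 0
  else rep(TRUE, nrow(bundle$phenotypes))
}

# assemble a covariate matrix from phenotype columns + cell PCs; "All"
# analyses additionally adjust for the lipid-lowering medication flag
build_covariates <- function(bundle, covariates, analysis_set,
                             pcs = TRUE) {
  ph <- bundle$phenotypes
  cols <- lapply(covariates, function(v) {
    if (!v %in% names(ph)) stop("unknown covariate column: ", v)
    x <- ph[[v]]
    if (v == "sex") as.numeric(x == 2) else as.numeric(x)
  })
  X <- do.call(cbind, cols)
  colnames(X) <- covariates
  if (analysis_set == "All" && "lipid_med" %in% names(ph) &&
      !"lipid_med" %in% covariates)
    X <- cbind(X, lipid_med = ph$lipid_med)
  for (v in c("htn_med", "dm_med"))
    if (v %in% names(ph) && !v %in% covariates)
      X <- cbind(X, setNames(data.frame(ph[[v]]), v))
  X <- as.matrix(X)
  if (pcs) {
    if (is.null(bundle$cell_pcs))
      stop("cell-type PCs not computed; call add_cell_pcs() first")
    X <- cbind(X, bundle$cell_pcs$scores)
  }
  X
}

#' Attach cell-type PCs to a bundle
#'
#' @param bundle a `cohort_bundle`
#' @param k number of PCs (default 5)
#' @return the bundle with `$cell_pcs` set
#' @export
add_cell_pcs <- function(bundle, k = 5) {
  bundle$cell_pcs <- celltype_pcs(bundle$methylation, k = k)
  bundle
}

#' Select representative probes among correlated significant loci
#'
#' Single-linkage clustering of significant probes on the distance
#' `1 - |Pearson r|`, cut so that probes joined by any path of pairwise
#' `|r| >= r_threshold` share a cluster; the probe with the smallest EWAS
#' p-value represents each cluster (ties broken by probe id).
#'
#' @param summary an `ewas_summary`
#' @param meth beta matrix containing the significant probes
#' @param r_threshold absolute-correlation threshold (default 0.8)
#' @return character vector of representative probe ids; the full cluster
#'   assignment is attached as attribute `clusters`
#' @export
select_representative_loci <- function(summary, meth, r_threshold = 0.8) {
  sig <- summary$significant_probes
  if (!length(sig)) stop("no significant probes to cluster")
  if (length(sig) == 1) {
    return(structure(sig, clusters = setNames(1L, sig)))
  }
  R <- abs(cor(meth[, sig, drop = FALSE], use = "pairwise.complete.obs"))
  hc <- hclust(as.dist(1 - R), method = "single")
  cl <- cutree(hc, h = 1 - r_threshold)
  pvals <- summary$results$p[match(sig, summary$results$predictor_id)]
  reps <- vapply(split(seq_along(sig), cl), function(idx) {
    cand <- sig[idx][order(pvals[idx], sig[idx])]
    cand[1]
  }, character(1))
  structure(unname(reps), clusters = cl)
}

#' Map exposures onto DMSs across exams and analysis sets
#'
#' For each DMS (methylation as the response) and each exposure variable
#' (predictor), fits the kinship mixed model per exam and analysis set.
#' Models at exams earlier than the reference exam additionally adjust for
#' age at the reference exam (methylation was measured then). Per exam the
#' effective number of tests of that exam's exposure panel calibrates the
#' Bonferroni threshold `alpha / meff`.
#'
#' @param bundle a `cohort_bundle` (with cell PCs)
#' @param dms_list probe ids to use as responses
#' @param exposure_vars exposure columns to test (default: all panel
#'   columns)
#' @param covariates phenotype covariates (default sex and age)
#' @param analysis_sets subset of c("All", "NoLipidMed")
#' @param exams exam labels (default: all panel exams)
#' @param alpha family-wise error rate per DMS (default 0.05)
#' @return list of class `association_grid`: `grid` (long data.frame with
#'   a `significant` flag), `meff` (per exam), `threshold` (per exam),
#'   `alpha`
#' @export
map_exposures <- function(bundle, dms_list, exposure_vars = NULL,
                          covariates = c("sex", "age"),
                          analysis_sets = c("All", "NoLipidMed"),
                          exams = NULL, alpha = 0.05) {
  if (!length(dms_list)) stop("dms_list must be nonempty")
  panel_exams <- attr(bundle$exposures, "exams")
  if (is.null(exams)) exams <- panel_exams
  missing_ex <- setdiff(exams, panel_exams)
  if (length(missing_ex)) {
    warning("exam(s) not in panel skipped: ",
            paste(missing_ex, collapse = ", "))
    exams <- intersect(exams, panel_exams)
  }
  ref <- panel_exams[length(panel_exams)]
  meff <- numeric(0); thr <- numeric(0)
  rows <- list()
  for (ex in exams) {
    expo <- bundle$exposures[[ex]]
    if (is.null(exposure_vars)) vars <- colnames(expo)
    else vars <- intersect(exposure_vars, colnames(expo))
    me <- effective_tests(expo[, vars, drop = FALSE])
    meff[ex] <- me$meff
    thr[ex] <- bonferroni_threshold(alpha, me$meff)
    for (aset in analysis_sets) {
      sel <- analysis_subset(bundle, aset)
      covar <- build_covariates(bundle, covariates, aset)
      # earlier exams: methylation was measured at the reference exam, so
      # keep adjusting for age at that exam (already the age column)
      for (dms in dms_list) {
        y <- bundle$methylation[, dms]
        r <- association_scan(y[sel],
                              as.matrix(expo[sel, vars, drop = FALSE]),
                              covar[sel, , drop = FALSE],
                              subset_kinship(bundle$kinship, sel),
                              response_id = dms, exam = ex,
                              analysis_set = aset)
        rows[[length(rows) + 1L]] <- r
      }
    }
  }
  grid <- do.call(rbind, rows)
  grid$significant <- !is.na(grid$p) & grid$p <= thr[grid$exam]
  structure(list(grid = grid, meff = meff, threshold = thr, alpha = alpha),
            class = "association_grid")
}

#' Count significant associations and rank exposures
#'
#' @param grid an `association_grid` from [map_exposures()]
#' @return list: `counts` (per DMS x exam x analysis set), `totals`
#'   (per DMS per analysis set, summed over exams), `ranking` (exposures by
#'   total significant associations), `unique_pairs` (count of distinct
#'   significant (DMS, exposure) pairs per analysis set)
#' @export
count_and_rank <- function(grid) {
  g <- data.table::as.data.table(grid$grid)
  counts <- g[, .(n_significant = sum(significant, na.rm = TRUE)),
              by = .(response_id, exam, analysis_set)]
  totals <- g[, .(total = sum(significant, na.rm = TRUE)),
              by = .(response_id, analysis_set)]
  ranking <- g[, .(n_associations = sum(significant, na.rm = TRUE)),
               by = .(predictor_id, analysis_set)]
  data.table::setorder(ranking, analysis_set, -n_associations, predictor_id)
  uniq <- g[significant == TRUE,
            .(unique_pairs = data.table::uniqueN(paste(response_id,
                                                       predictor_id))),
            by = .(analysis_set)]
  list(counts = as.data.frame(counts), totals = as.data.frame(totals),
       ranking = as.data.frame(ranking), unique_pairs = as.data.frame(uniq))
}

#' Association between one DMS and expression of its target gene
#'
#' Mixed-model fit of transcript expression on the probe's beta value with
#' sex, age, and cell-type PC adjustment, restricted to samples present in
#' the expression table (typically a medication-free subset).
#'
#' @param bundle a `cohort_bundle` with `$expression`
#' @param dms probe id (predictor)
#' @param transcript expression column id
#' @param covariates phenotype covariates (default sex, age)
#' @return one-row `association_result` data.frame
#' @export
dms_expression_assoc <- function(bundle, dms, transcript,
                                 covariates = c("sex", "age")) {
  if (is.null(bundle$expression)) stop("bundle has no expression table")
  if (!transcript %in% colnames(bundle$expression))
    stop("transcript not found: ", transcript)
  if (!dms %in% colnames(bundle$methylation))
    stop("probe not found: ", dms)
  ids <- rownames(bundle$expression)
  sel <- match(ids, bundle$phenotypes$sample_id)
  covar <- build_covariates(bundle, covariates, "NoLipidMed")[sel, ,
                                                             drop = FALSE]
  y <- bundle$expression[, transcript]
  x <- bundle$methylation[ids, dms, drop = FALSE]
  association_scan(y, x, covar, subset_kinship(bundle$kinship, sel),
                   response_id = transcript,
                   exam = reference_exam(bundle),
                   analysis_set = "expression_subset")
}
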