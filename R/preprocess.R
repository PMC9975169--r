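#' QC-filter methylation probes
#'
#' Removes probes on sex chromosomes (when `autosomes_only`) and probes
#' whose missing fraction exceeds `max_missing_fraction`. The removal
#' report per rule is attached as attribute `qc_report` (data.frame:
#' rule, probes_removed).
#'
#' @param meth samples x probes beta matrix (NAs allowed)
#' @param ann probe annotation covering all probes
#' @param max_missing_fraction maximum tolerated per-probe missing fraction
#'   (default 0.05)
#' @param autosomes_only drop chromosomes X and Y (default TRUE)
#' @return filtered beta matrix with `qc_report` attribute
#' @export
qc_filter_probes <- function(meth, ann, max_missing_fraction = 0.05,
                             autosomes_only = TRUE) {
  probes <- colnames(meth)
  miss_ann <- setdiff(probes, ann$probe_id)
  if (length(miss_ann))
    stop("annotation missing for probe(s): ",
         paste(utils::head(miss_ann, 5), collapse = ", "))
  chr <- ann$chromosome[match(probes, ann$probe_id)]
  sex_chr <- autosomes_only & chr %in% c("X", "Y", "chrX", "chrY", "23", "24")
  miss_frac <- colMeans(is.na(meth))
  too_missing <- !sex_chr & miss_frac > max_missing_fraction
  keep <- !sex_chr & !too_missing
  if (!any(keep)) stop("all probes removed by QC")
  out <- meth[, keep, drop = FALSE]
  attr(out, "qc_report") <- data.frame(
    rule = c("sex_chromosome", "missingness"),
    probes_removed = c(sum(sex_chr), sum(too_missing)))
  out
}

#' Cell-type principal components of the beta matrix
#'
#' PCs of the column-centered (not scaled: betas share a common [0,1]
#' scale) beta matrix over samples, used as covariates to absorb cell-type
#' composition heterogeneity. Missing betas are mean-imputed per probe for
#' the extraction only. Sign convention: within each PC the loading of
#' largest magnitude is made positive, so scores are reproducible across
#' platforms.
#'
#' @param meth samples x probes beta matrix
#' @param k number of components (default 5)
#' @return list of class `cell_pcs`: `scores` (samples x k, columns
#'   `PC1..PCk`) and `explained_variance_fraction`
#' @export
celltype_pcs <- function(meth, k = 5) {
  n <- nrow(meth)
  if (k >= n) stop("k must be smaller than the number of samples")
  if (k >= ncol(meth)) stop("k must be smaller than the number of probes")
  if (anyNA(meth)) {
    mu <- colMeans(meth, na.rm = TRUE)
    idx <- which(is.na(meth), arr.ind = TRUE)
    meth[idx] <- mu[idx[, 2]]
  }
  pc <- prcomp(meth, center = TRUE, scale. = FALSE, rank. = k)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  scores <- sweep(pc$x[, seq_len(k), drop = FALSE], 2, flip, `*`)
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- rownames(meth)
  structure(list(scores = scores,
                 explained_variance_fraction =
                   (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]),
            class = "cell_pcs")
}

#' log10-transform triglyceride values
#'
#' @param tg_mg_dl positive TG values in mg/dL; names (sample ids) are kept
#' @return log10-transformed values
#' @export
transform_tg <- function(tg_mg_dl) {
  bad <- which(!is.na(tg_mg_dl) & tg_mg_dl <= 0)
  if (length(bad)) {
    lab <- if (!is.null(names(tg_mg_dl))) names(tg_mg_dl)[bad] else bad
    stop("nonpositive TG for sample(s): ", paste(lab, collapse = ", "))
  }
  log10(tg_mg_dl)
}

#' Convert nutrient intake to percent of total energy
#'
#' Atwater factors: alcohol 7, carbohydrate 4, protein 4, fat 9 kcal/g.
#'
#' @param amount intake in g/day
#' @param kind one of "alcohol", "carbohydrate", "fat", "protein"
#' @param total_energy total energy intake in kcal/day (> 0)
#' @return percent of total energy
#' @export
normalize_to_energy <- function(amount,
                                kind = c("alcohol", "carbohydrate", "fat",
                                         "protein"),
                                total_energy) {
  kind <- match.arg(kind)
  if (any(total_energy <= 0, na.rm = TRUE))
    stop("total_energy must be positive")
  kcal_per_g <- c(alcohol = 7, carbohydrate = 4, fat = 9, protein = 4)
  100 * amount * kcal_per_g[[kind]] / total_energy
}
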