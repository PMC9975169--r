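# draw family-structured random effects for n samples x p columns:
# N(0, var * 2*Phi), exploiting block-diagonality of the kinship matrix
draw_family_effects <- function(chol_blocks, n, p, var) {
  if (var <= 0) return(matrix(0, n, p))
  eff <- matrix(rnorm(n * p), n, p)
  for (b in chol_blocks)
    eff[b$rows, ] <- crossprod(b$L, eff[b$rows, , drop = FALSE])
  eff * sqrt(var)
}

# upper Cholesky factors of 2*Phi per family block
kinship_chol_blocks <- function(kin) {
  fam <- attr(kin, "family")
  if (is.null(fam)) fam <- rep("all", nrow(kin))
  lapply(split(seq_len(nrow(kin)), fam), function(rows) {
    list(rows = rows, L = chol(2 * unclass(kin)[rows, rows, drop = FALSE]))
  })
}

#' Generate cell-type mixture methylation with planted exposure effects
#'
#' Each probe has a baseline methylation level per cell type; the observed
#' beta value of a sample is the mixture of those baselines under the
#' sample's Dirichlet cell-type weights, plus a family (kinship) random
#' effect, plus planted exposure effects at mediator probes (linear on the
#' beta scale, driven by alcohol g/day and carbohydrate %energy at the
#' reference exam), plus residual noise, truncated to [0,1]. The truncated
#' fraction is reported so planted effects can be kept in the linear regime.
#'
#' @param ped pedigree (same samples as `exposures`)
#' @param exposures panel from [generate_exposures()]
#' @param cfg a [sim_config()]
#' @param kin optional precomputed kinship matrix
#' @return list with `meth` (samples x probes beta matrix), `cellmix`
#'   (list: `weights` n x K, `baselines` P x K), `truth` (truth table,
#'   see Details), and `annotation` (probe annotation data.frame)
#' @details The truth table has one row per (mediator probe, exposure) with
#'   the planted `alpha1`, `theta1`, `theta2`, `theta3`, the default
#'   contrast (`a_star` = exposure mean, `a` = mean + 1 SD at the reference
#'   exam), and the implied `nde`, `nie`, `te` with `te = nde + nie`
#'   exactly.
#' @export
generate_methylation <- function(ped, exposures, cfg, kin = NULL) {
  n <- nrow(ped)
  P <- cfg$n_probes
  K <- cfg$n_celltypes
  med <- cfg$mediators
  if (is.null(kin)) kin <- kinship_from_pedigree(ped)
  stopifnot(identical(rownames(exposures[[1]]), ped$id))

  # per-probe baseline: bimodal across probes, as on methylation arrays
  base <- 0.05 + 0.9 * stats::rbeta(P, 0.4, 0.4)
  B <- clamp(base + cfg$celltype_profile_sd * matrix(rnorm(P * K), P, K),
             0.02, 0.98)
  W <- rdirichlet(n, cfg$dirichlet_concentration)
  M <- tcrossprod(W, B)  # n x P mixture means

  M <- M + draw_family_effects(kinship_chol_blocks(kin), n, P,
                               cfg$meth_sigma_g2)

  ref <- exam_labels(cfg$n_exams)[cfg$n_exams]
  alc <- exposures[[ref]][, "alcohol_g_d"]
  carb <- exposures[[ref]][, "carb_pct_energy"]
  jmed <- seq_len(nrow(med))  # mediator probes occupy the first columns
  for (j in jmed)
    M[, j] <- M[, j] + med$alpha_alcohol[j] * alc + med$alpha_carb[j] * carb

  M <- M + sqrt(cfg$meth_sigma_e2) * matrix(rnorm(n * P), n, P)
  truncated <- mean(M < 0 | M > 1)
  if (truncated > 0)
    message(sprintf("generate_methylation: %.3f%% of beta values truncated to [0,1]",
                    100 * truncated))
  M <- clamp(M, 0, 1)

  probe_ids <- c(med$probe, sprintf("cgS%05d", seq_len(P - nrow(med))))
  dimnames(M) <- list(ped$id, probe_ids)
  rownames(B) <- probe_ids

  truth <- build_truth(med, alc, carb, M, cfg)
  ann <- simulate_annotation(probe_ids, med)
  list(meth = M, cellmix = list(weights = W, baselines = B),
       truth = truth, annotation = ann,
       truncated_fraction = truncated)
}

build_truth <- function(med, alc, carb, M, cfg) {
  one <- function(expo, avec, alpha, theta1) {
    a_star <- mean(avec); a <- a_star + sd(avec)
    mbar <- colMeans(M[, seq_len(nrow(med)), drop = FALSE])
    th3 <- if (expo == "alcohol_g_d") cfg$theta3 else 0
    nde <- (theta1 + th3 * mbar) * (a - a_star)
    nie <- (med$theta2 * med[[alpha]] + th3 * med[[alpha]] * a) * (a - a_star)
    data.frame(probe = med$probe, exposure = expo,
               alpha1 = med[[alpha]], theta1 = theta1,
               theta2 = med$theta2, theta3 = th3,
               a_star = a_star, a = a,
               nde = nde, nie = nie, te = nde + nie,
               stringsAsFactors = FALSE)
  }
  rbind(one("alcohol_g_d", alc, "alpha_alcohol", cfg$theta1_alcohol),
        one("carb_pct_energy", carb, "alpha_carb", cfg$theta1_carb))
}

simulate_annotation <- function(probe_ids, med) {
  P <- length(probe_ids)
  nf <- P - nrow(med)
  regions <- c("TSS1500", "5UTR", "genic", "3UTR", "intergenic")
  rel <- c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf", "OpenSea")
  filler <- data.frame(
    probe_id = probe_ids[-seq_len(nrow(med))],
    chromosome = as.character(sample(1:22, nf, replace = TRUE)),
    position = sample.int(2e8, nf, replace = TRUE),
    gene = ifelse(runif(nf) < 0.75, sprintf("GENE%04d", seq_len(nf)), ""),
    genic_region = sample(regions, nf, replace = TRUE,
                          prob = c(0.1, 0.1, 0.45, 0.1, 0.25)),
    cpg_relation = sample(rel, nf, replace = TRUE,
                          prob = c(0.3, 0.1, 0.1, 0.05, 0.05, 0.4)),
    stringsAsFactors = FALSE)
  filler$genic_region[filler$gene == "" & filler$genic_region != "intergenic"] <-
    "intergenic"
  filler$gene[filler$genic_region == "intergenic"] <- ""
  known <- data.frame(
    probe_id = med$probe, chromosome = med$chromosome,
    position = med$position, gene = med$gene,
    genic_region = med$genic_region, cpg_relation = med$cpg_relation,
    stringsAsFactors = FALSE)
  rbind(known, filler)
}
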