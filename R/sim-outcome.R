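#' Generate the TG outcome and phenotype covariates
#'
#' log10(TG) is built from the planted direct exposure effects (alcohol
#' g/day and carbohydrate %energy at the reference exam), the mediator-probe
#' effects `theta2` on the beta scale, an optional alcohol x mediator
#' interaction `theta3`, covariate effects (sex, age, BMI, smoking,
#' physical activity), a cell-composition effect (confounding via mixture
#' proportions), a family random effect with covariance `2 Phi sigma_g2`,
#' and residual noise. The intercept is chosen so that mean TG is about
#' 112 mg/dL; the stored TG column is on the mg/dL scale.
#'
#' @param ped pedigree
#' @param exposures exposure panel
#' @param meth beta matrix from [generate_methylation()]
#' @param cellmix cell mixture list (`weights` used for the confounder term)
#' @param cfg a [sim_config()]
#' @param kin optional precomputed kinship matrix
#' @return phenotype data.frame (one row per sample): `sample_id`, `fam`,
#'   `sex`, `age`, `bmi`, `smoking_cig_d`, `phys_activity`, `lipid_med`,
#'   `htn_med`, `dm_med`, `tg_mgdl`
#' @export
generate_outcome <- function(ped, exposures, meth, cellmix, cfg, kin = NULL) {
  n <- nrow(ped)
  if (is.null(kin)) kin <- kinship_from_pedigree(ped)
  ref <- exam_labels(cfg$n_exams)[cfg$n_exams]
  alc <- exposures[[ref]][, "alcohol_g_d"]
  carb <- exposures[[ref]][, "carb_pct_energy"]
  med <- cfg$mediators
  Mm <- meth[, med$probe, drop = FALSE]

  sex <- ped$sex
  age <- runif(n, 40, 90)
  bmi <- clamp(rnorm(n, 28, 4.5), 17, 48)
  smoking <- exposures[[ref]][, "smoking_cig_d"]
  phys <- exposures[[ref]][, "phys_activity"]
  lipid_med <- rbinom(n, 1, cfg$lipid_med_prob)
  htn_med <- rbinom(n, 1, cfg$htn_med_prob)
  dm_med <- rbinom(n, 1, cfg$dm_med_prob)

  Wc <- sweep(cellmix$weights, 2, colMeans(cellmix$weights))
  lin <- cfg$theta1_alcohol * alc + cfg$theta1_carb * carb +
    drop(Mm %*% med$theta2) +
    cfg$theta3 * alc * rowSums(Mm) +
    0.05 * (sex == 2) + 0.0015 * age + 0.008 * bmi +
    0.0008 * smoking - 0.0008 * phys +
    drop(Wc %*% cfg$celltype_outcome_effect)
  theta0 <- 2.05 - mean(lin)
  y <- theta0 + lin +
    drop(draw_family_effects(kinship_chol_blocks(kin), n, 1, cfg$sigma_g2)) +
    rnorm(n, 0, sqrt(cfg$sigma_e2))

  data.frame(sample_id = ped$id, fam = ped$fam, sex = sex, age = age,
             bmi = bmi, smoking_cig_d = smoking, phys_activity = phys,
             lipid_med = lipid_med, htn_med = htn_med, dm_med = dm_med,
             tg_mgdl = 10^y, stringsAsFactors = FALSE)
}

#' Generate PBMC-style expression for mediator genes
#'
#' One transcript per mediator probe with a non-empty gene symbol;
#' expression is a linear function of the probe's beta value plus noise.
#' By default the first eight gene-bearing mediators couple negatively
#' (methylation suppresses expression) and the remainder are uncoupled,
#' mimicking the mixed picture seen in blood transcriptome data.
#'
#' @param meth beta matrix
#' @param mediators mediator table (probe, gene columns used)
#' @param coupling optional numeric vector of couplings per gene-bearing
#'   mediator probe (expression units per beta unit)
#' @param noise_sd residual expression SD
#' @return samples x transcripts matrix; column names `GENE_probe`
#' @export
generate_expression <- function(meth, mediators,
                                coupling = NULL, noise_sd = 0.5) {
  withgene <- mediators[mediators$gene != "", , drop = FALSE]
  k <- nrow(withgene)
  if (is.null(coupling))
    coupling <- c(rep(-1.5, min(8, k)), rep(0, max(0, k - 8)))
  stopifnot(length(coupling) == k)
  n <- nrow(meth)
  expr <- sapply(seq_len(k), function(i) {
    8 + coupling[i] * meth[, withgene$probe[i]] + rnorm(n, 0, noise_sd)
  })
  colnames(expr) <- paste(withgene$gene, withgene$probe, sep = "_")
  rownames(expr) <- rownames(meth)
  attr(expr, "coupling") <- setNames(coupling, colnames(expr))
  expr
}

#' Simulate a complete synthetic family cohort
#'
#' Runs the full generative chain (pedigree -> kinship -> exposures ->
#' methylation -> outcome -> optional expression) under one seed and
#' assembles a `cohort_bundle` directly usable by every analysis stage.
#'
#' @param cfg a [sim_config()]
#' @param expression logical: also simulate mediator-gene expression
#' @return a `cohort_bundle` list: `methylation`, `annotation`,
#'   `phenotypes`, `exposures`, `kinship`, `pedigree`, `truth`, `cellmix`,
#'   optional `expression`
#' @export
simulate_cohort <- function(cfg = sim_config(), expression = FALSE) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  ped <- generate_pedigree(cfg$n_families, cfg$family_size)
  kin <- kinship_from_pedigree(ped)
  expo <- generate_exposures(ped, cfg)
  gm <- generate_methylation(ped, expo, cfg, kin = kin)
  phen <- generate_outcome(ped, expo, gm$meth, gm$cellmix, cfg, kin = kin)
  bundle <- list(methylation = gm$meth, annotation = gm$annotation,
                 phenotypes = phen, exposures = expo, kinship = kin,
                 pedigree = ped, truth = gm$truth, cellmix = gm$cellmix,
                 config = cfg)
  if (expression)
    bundle$expression <- generate_expression(gm$meth, cfg$mediators)
  class(bundle) <- "cohort_bundle"
  bundle
}
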