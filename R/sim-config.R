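#' Default planted mediation effects at known TG-associated CpGs
#'
#' Twelve CpG sites repeatedly reported as associated with plasma
#' triglyceride and with alcohol and/or carbohydrate intake in population
#' cohorts, with literature-scale effect sizes: `alpha_alcohol` is the
#' exposure effect on the methylation beta value per g/day of alcohol,
#' `alpha_carb` per percent of energy from carbohydrate (zero where the site
#' is not a mediator for that exposure), and `theta2` the effect of the beta
#' value on log10 TG (mg/dL). Alcohol hypomethylates most sites while
#' carbohydrate acts in the opposite direction, so with negative `theta2`
#' the mediated (indirect) effect of alcohol on TG is positive and that of
#' carbohydrate negative at the shared sites.
#'
#' @return data.frame with columns `probe`, `chromosome`, `position`,
#'   `gene`, `genic_region`, `cpg_relation`, `alpha_alcohol`, `alpha_carb`,
#'   `theta2`
#' @export
default_mediator_effects <- function() {
  data.frame(
    probe = c("cg03725309", "cg14476101", "cg19693031", "cg06690548",
              "cg21429551", "cg07504977", "cg11376147", "cg00574958",
              "cg20544516", "cg08129017", "cg22304262", "cg06500161"),
    chromosome = c("1", "1", "1", "4", "7", "10", "11", "11", "17", "17",
                   "19", "21"),
    position = c(109757585L, 120255992L, 145441552L, 139162808L, 30635762L,
                 102131012L, 57261198L, 68607622L, 17717183L, 17728660L,
                 47287778L, 43656587L),
    gene = c("SARS", "PHGDH", "TXNIP", "SLC7A11", "GARS", "",
             "SLC43A1", "CPT1A", "SREBF1", "SREBF1", "SLC1A5", "ABCG1"),
    genic_region = c("genic", "genic", "3UTR", "genic", "genic",
                     "intergenic", "genic", "5UTR", "genic", "genic",
                     "5UTR", "genic"),
    cpg_relation = c("S_Shore", "S_Shore", "OpenSea", "OpenSea", "S_Shore",
                     "N_Shelf", "OpenSea", "N_Shore", "S_Shore", "S_Shore",
                     "N_Shelf", "S_Shore"),
    alpha_alcohol = c(-0.00031, -0.00118, -0.00065, -0.00183, -0.00077,
                      0, -0.00025, -0.00012, 0.00018, 0.00029,
                      -0.00055, 0.00015),
    alpha_carb = c(0.00039, 0.00099, 0.00060, 0.00163, 0.00055,
                   -0.00064, 0.00025, 0.00028, 0, -0.00037,
                   0, -0.00047),
    theta2 = c(-0.695, -0.420, -0.440, -0.514, -0.466, 0.503,
               -1.494, -2.875, 0.774, 0.547, -0.500, 1.071),
    stringsAsFactors = FALSE)
}

#' Simulation configuration for the synthetic family cohort
#'
#' Defines the generative model for a family-based methylation cohort:
#' nuclear-family pedigrees with kinship random effects, six-cell-type
#' mixture structure in beta values, a block-correlated longitudinal
#' exposure panel observed at four exams, and exposure -> CpG -> log10(TG)
#' mediation chains with configurable coefficients.
#'
#' @param n_families number of nuclear families (2 founders + children each)
#' @param family_size min/max children per family
#' @param n_probes total CpG probes simulated
#' @param n_celltypes number of cell types mixed per sample
#' @param dirichlet_concentration Dirichlet concentration per cell type;
#'   the default mimics whole-blood composition (granulocyte-dominated)
#' @param n_exams number of repeated exposure exams; the last is the
#'   reference exam at which methylation and TG are measured
#' @param n_exposures width of the exposure panel per exam
#' @param exposure_block_sizes sizes of equicorrelated exposure blocks
#'   (unassigned variables are independent)
#' @param exposure_block_rho within-block latent correlation, in [0,1)
#' @param exam_autocorrelation across-exam AR(1) persistence of each
#'   variable's latent score, in [0,1]
#' @param mediators data.frame of planted mediator effects (columns as in
#'   [default_mediator_effects()]); `NULL` builds one from the scalar
#'   `alpha1`/`theta2` arguments with `n_mediator_probes` synthetic probes
#' @param n_mediator_probes number of mediator probes when `mediators` is
#'   built from scalars
#' @param alpha1 scalar mediator-model alcohol effect (beta units per g/day)
#'   used when `mediators` is NULL
#' @param theta1_alcohol,theta1_carb direct exposure effects on log10 TG
#'   (per g/day and per percent energy respectively)
#' @param theta2 scalar mediator effect on log10 TG used when `mediators`
#'   is NULL
#' @param theta3 exposure x mediator interaction coefficient (default 0)
#' @param sigma_g2 family (kinship) variance of log10 TG
#' @param sigma_e2 residual variance of log10 TG
#' @param meth_sigma_g2 family variance per probe on the beta scale
#' @param meth_sigma_e2 residual variance per probe on the beta scale
#' @param celltype_profile_sd spread of per-probe cell-type baseline offsets
#'   (beta units); controls how strongly mixtures drive between-sample
#'   variance
#' @param celltype_outcome_effect length-`n_celltypes` effect of mixture
#'   proportions on log10 TG; nonzero values confound naive EWAS scans the
#'   way blood-count variation does in real cohorts
#' @param alcohol_zero_prob point mass at zero for alcohol intake
#' @param lipid_med_prob,htn_med_prob,dm_med_prob medication flag rates
#' @param seed integer seed driving all randomness
#' @return a validated `sim_config` list
#' @export
sim_config <- function(n_families = 500,
                       family_size = c(min = 1, max = 3),
                       n_probes = 2000,
                       n_celltypes = 6,
                       dirichlet_concentration = c(30, 7.5, 4, 4, 2.5, 2.5),
                       n_exams = 4,
                       n_exposures = 300,
                       exposure_block_sizes = rep(10L, 29),
                       exposure_block_rho = 0.6,
                       exam_autocorrelation = 0.8,
                       mediators = default_mediator_effects(),
                       n_mediator_probes = 12,
                       alpha1 = -0.0018,
                       theta1_alcohol = 0.001,
                       theta1_carb = 0.0015,
                       theta2 = -0.5,
                       theta3 = 0,
                       sigma_g2 = 0.01,
                       sigma_e2 = 0.04,
                       meth_sigma_g2 = 2e-4,
                       meth_sigma_e2 = 4e-4,
                       celltype_profile_sd = 0.15,
                       celltype_outcome_effect = c(0.7, -0.4, 0.3, -0.3,
                                                   0.2, -0.2),
                       alcohol_zero_prob = 0.3,
                       lipid_med_prob = 0.45,
                       htn_med_prob = 0.40,
                       dm_med_prob = 0.12,
                       seed = 1L) {
  if (is.null(mediators)) {
    stopifnot(n_mediator_probes >= 1)
    mediators <- data.frame(
      probe = sprintf("cgSIM%05d", seq_len(n_mediator_probes)),
      chromosome = as.character(rep_len(1:22, n_mediator_probes)),
      position = 1e6L + seq_len(n_mediator_probes),
      gene = sprintf("SIMGENE%d", seq_len(n_mediator_probes)),
      genic_region = "genic", cpg_relation = "OpenSea",
      alpha_alcohol = alpha1, alpha_carb = 0, theta2 = theta2,
      stringsAsFactors = FALSE)
  }
  cfg <- list(
    n_families = as.integer(n_families), family_size = family_size,
    n_probes = as.integer(n_probes), n_celltypes = as.integer(n_celltypes),
    dirichlet_concentration = dirichlet_concentration,
    n_exams = as.integer(n_exams), n_exposures = as.integer(n_exposures),
    exposure_block_sizes = as.integer(exposure_block_sizes),
    exposure_block_rho = exposure_block_rho,
    exam_autocorrelation = exam_autocorrelation,
    mediators = mediators,
    theta1_alcohol = theta1_alcohol, theta1_carb = theta1_carb,
    theta3 = theta3,
    sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
    meth_sigma_g2 = meth_sigma_g2, meth_sigma_e2 = meth_sigma_e2,
    celltype_profile_sd = celltype_profile_sd,
    celltype_outcome_effect = celltype_outcome_effect,
    alcohol_zero_prob = alcohol_zero_prob,
    lipid_med_prob = lipid_med_prob, htn_med_prob = htn_med_prob,
    dm_med_prob = dm_med_prob,
    seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_families < 1) stop("n_families must be >= 1")
    if (any(c(sigma_g2, sigma_e2, meth_sigma_g2, meth_sigma_e2) < 0))
      stop("variance components must be >= 0")
    if (any(dirichlet_concentration <= 0))
      stop("dirichlet_concentration must be strictly positive")
    if (length(dirichlet_concentration) != n_celltypes)
      stop("dirichlet_concentration length must equal n_celltypes")
    if (length(celltype_outcome_effect) != n_celltypes)
      stop("celltype_outcome_effect length must equal n_celltypes")
    if (sum(exposure_block_sizes) > n_exposures - 10)
      stop("sum of exposure_block_sizes exceeds the generic panel width ",
           "(n_exposures - 10 named variables)")
    if (exposure_block_rho < 0 || exposure_block_rho >= 1)
      stop("exposure_block_rho must be in [0,1)")
    if (exam_autocorrelation < 0 || exam_autocorrelation > 1)
      stop("exam_autocorrelation must be in [0,1]")
    if (nrow(mediators) > n_probes)
      stop("more mediator probes than probes")
    if (alcohol_zero_prob < 0 || alcohol_zero_prob >= 1)
      stop("alcohol_zero_prob must be in [0,1)")
  })
  invisible(cfg)
}

# exam labels: last exam is the reference ("exam 8" style numbering)
exam_labels <- function(n_exams) paste0("exam", seq(9 - n_exams, 8))
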