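#' Configuration for a discovery or replication run
#'
#' Exactly one of `sim` (a [sim_config()] for a synthetic cohort) or
#' `paths` (input files for [load_bundle()]) must be given.
#'
#' @param sim optional [sim_config()]
#' @param paths optional named list of input paths
#' @param ewas_threshold epigenome-wide significance threshold
#' @param exposure_alpha family-wise rate per DMS for exposure mapping
#'   (calibrated by Meff)
#' @param mediation_alpha family-wise rate per exposure for mediation
#' @param r_threshold absolute-correlation threshold for representative-
#'   locus clustering
#' @param k_pcs number of cell-type PCs
#' @param max_missing_fraction probe QC missingness threshold
#' @param n_boot bootstrap replicates for mediation CIs
#' @param mediation_exposures exposures carried into the mediation stage
#' @param seed integer seed
#' @param out output directory (NULL: nothing written)
#' @return a `run_config` list
#' @export
run_config <- function(sim = NULL, paths = NULL,
                       ewas_threshold = 1.1e-7,
                       exposure_alpha = 0.05,
                       mediation_alpha = 0.05,
                       r_threshold = 0.8, k_pcs = 5,
                       max_missing_fraction = 0.05,
                       n_boot = 200,
                       mediation_exposures = c("alcohol_pct_energy",
                                               "carb_pct_energy"),
                       seed = 1L, out = NULL) {
  if (is.null(sim) == is.null(paths))
    stop("exactly one of `sim` or `paths` must be supplied")
  for (a in c(exposure_alpha, mediation_alpha))
    if (a <= 0 || a >= 1) stop("alphas must be in (0,1)")
  structure(list(sim = sim, paths = paths, ewas_threshold = ewas_threshold,
                 exposure_alpha = exposure_alpha,
                 mediation_alpha = mediation_alpha,
                 r_threshold = r_threshold, k_pcs = k_pcs,
                 max_missing_fraction = max_missing_fraction,
                 n_boot = n_boot,
                 mediation_exposures = mediation_exposures,
                 seed = as.integer(seed), out = out),
            class = "run_config")
}

prepare_bundle <- function(cfg) {
  bundle <- if (!is.null(cfg$sim)) {
    sc <- cfg$sim; sc$seed <- cfg$seed
    simulate_cohort(sc)
  } else load_bundle(cfg$paths)
  bundle$methylation <- qc_filter_probes(bundle$methylation,
                                         bundle$annotation,
                                         cfg$max_missing_fraction,
                                         autosomes_only = TRUE)
  add_cell_pcs(bundle, k = cfg$k_pcs)
}

#' Run the three-step discovery pipeline
#'
#' Stages: probe QC and cell-type PCs; EWAS for log10 TG in both analysis
#' sets with Bonferroni control; representative-locus selection among the
#' significant probes; effective-number-of-tests calibration and exposure
#' mapping of the representatives across all exams; association counting
#' and exposure ranking; mediation of the top exposures through the
#' representative DMSs each is associated with. When `cfg$out` is set,
#' every table is written as TSV with a provenance header carrying the
#' config hash; reruns with an identical config are byte-identical.
#'
#' @param cfg a [run_config()]
#' @return list of class `report_bundle`
#' @export
run_discovery <- function(cfg) {
  t0 <- Sys.time()
  bundle <- prepare_bundle(cfg)
  stage_log <- function(stage, ...) {
    message(sprintf("[%s] %s | %.1fs elapsed", stage, sprintf(...),
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  stage_log("prepare", "n=%d samples, %d probes after QC",
            nrow(bundle$methylation), ncol(bundle$methylation))

  ewas <- list(
    All = run_ewas(bundle, analysis_set = "All",
                   threshold = cfg$ewas_threshold),
    NoLipidMed = run_ewas(bundle, analysis_set = "NoLipidMed",
                          threshold = cfg$ewas_threshold))
  stage_log("ewas", "%d significant (All), %d (NoLipidMed)",
            length(ewas$All$significant_probes),
            length(ewas$NoLipidMed$significant_probes))

  reps <- character(0)
  grid <- NULL; counts <- NULL; medi <- NULL; mlv <- NA_real_
  if (length(ewas$All$significant_probes)) {
    reps <- select_representative_loci(ewas$All, bundle$methylation,
                                       cfg$r_threshold)
    stage_log("cluster", "%d significant probes -> %d representatives",
              length(ewas$All$significant_probes), length(reps))
    sel <- analysis_subset(bundle, "NoLipidMed")
    mlv <- multilocus_variance(
      transform_tg(bundle$phenotypes$tg_mgdl)[sel],
      bundle$methylation[sel, reps, drop = FALSE],
      build_covariates(bundle, c("sex", "age"), "NoLipidMed")[sel, ,
                                                             drop = FALSE],
      subset_kinship(bundle$kinship, sel))
    stage_log("variance", "representatives jointly explain %.1f%% of TG",
              mlv)

    grid <- map_exposures(bundle, reps, alpha = cfg$exposure_alpha)
    counts <- count_and_rank(grid)
    stage_log("exposure_map", "meff per exam: %s",
              paste(sprintf("%s=%.1f", names(grid$meff), grid$meff),
                    collapse = ", "))

    medi <- run_mediation_stage(bundle, cfg, grid, reps)
    stage_log("mediation", "%d cells estimated", NROW(medi))
  } else {
    stage_log("cluster", "no significant probes; downstream stages empty")
  }

  report <- structure(list(
    ewas = ewas, representatives = reps, multilocus_pct = mlv,
    grid = grid, counts = counts, mediation = medi,
    qc_report = attr(bundle$methylation, "qc_report"),
    config = cfg, config_hash = object_hash(strip_out(cfg)),
    truth = bundle$truth),
    class = "report_bundle")
  if (!is.null(cfg$out)) write_report(report, cfg$out)
  report
}

# mediators per exposure: representative DMSs with a significant exposure
# association in the no-medication set at any exam
run_mediation_stage <- function(bundle, cfg, grid, reps) {
  g <- grid$grid
  pick <- function(var) {
    raw <- if (var == "alcohol_pct_energy") "alcohol_g_d" else var
    unique(g$response_id[g$predictor_id == raw & g$significant &
                           g$analysis_set == "NoLipidMed"])
  }
  rows <- list()
  for (expo in cfg$mediation_exposures) {
    meds <- pick(expo)
    if (!length(meds)) {
      message("mediation: no associated DMSs for ", expo, "; skipped")
      next
    }
    rows[[expo]] <- mediation_grid(bundle, expo, meds,
                                   exams = reference_exam(bundle),
                                   n_boot = cfg$n_boot, seed = cfg$seed,
                                   alpha = cfg$mediation_alpha)
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

strip_out <- function(cfg) { cfg$out <- NULL; unclass(cfg) }

write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  h <- report$config_hash
  for (aset in names(report$ewas))
    write_table_prov(report$ewas[[aset]]$results,
                     file.path(dir, sprintf("ewas_%s.tsv", aset)), h)
  write_table_prov(data.frame(probe = report$representatives),
                   file.path(dir, "representatives.tsv"), h)
  if (!is.null(report$grid)) {
    write_table_prov(report$grid$grid, file.path(dir, "exposure_grid.tsv"), h)
    write_table_prov(data.frame(exam = names(report$grid$meff),
                                meff = unname(report$grid$meff),
                                threshold = unname(report$grid$threshold)),
                     file.path(dir, "meff.tsv"), h)
    write_table_prov(report$counts$counts, file.path(dir, "counts.tsv"), h)
    write_table_prov(report$counts$ranking, file.path(dir, "ranking.tsv"), h)
  }
  if (!is.null(report$mediation))
    write_table_prov(report$mediation, file.path(dir, "mediation.tsv"), h)
  writeLines(c(prov_line(h),
               sprintf("multilocus_variance_pct\t%.6f",
                       report$multilocus_pct)),
             file.path(dir, "summary.tsv"))
  invisible(dir)
}

#' Replicate the three mapping steps for a fixed DMS list
#'
#' Runs TG association (step 1), alcohol/carbohydrate association (step 2)
#' and mediation (step 3) restricted to `dms_list` on a replication cohort,
#' calling significance at uncorrected p <= 0.05 (validation convention).
#' Probes absent from the replication data are reported as untested.
#'
#' @param cfg a [run_config()] describing the replication cohort
#' @param dms_list probe ids from the discovery run
#' @param exposures exposures to replicate (default alcohol %energy and
#'   carbohydrate %energy)
#' @return list of class `replication_report`: `step1` (TG association),
#'   `step2` (exposure association), `step3` (mediation), `untested`
#' @export
run_replication <- function(cfg, dms_list,
                            exposures = c("alcohol_pct_energy",
                                          "carb_pct_energy")) {
  if (!length(dms_list)) stop("dms_list must be provided")
  bundle <- prepare_bundle(cfg)
  present <- intersect(dms_list, colnames(bundle$methylation))
  untested <- setdiff(dms_list, present)
  if (length(untested))
    message("replication: ", length(untested), " probe(s) untested: ",
            paste(untested, collapse = ", "))
  if (!length(present)) stop("no listed probes present in replication data")

  step1 <- run_ewas(bundle, analysis_set = "NoLipidMed", threshold = 0.05,
                    probes = present)
  raw <- vapply(exposures, function(e)
    if (e == "alcohol_pct_energy") "alcohol_g_d" else e, character(1))
  grid <- map_exposures(bundle, present, exposure_vars = unique(raw),
                        analysis_sets = "NoLipidMed",
                        exams = reference_exam(bundle))
  g <- grid$grid
  g$significant <- !is.na(g$p) & g$p <= 0.05  # uncorrected for validation
  step3 <- mediation_grid(bundle, exposures, present,
                          n_boot = cfg$n_boot, seed = cfg$seed)
  step3$threshold <- 0.05  # validation: uncorrected
  step3$significant <- is.finite(step3$p_nie) & step3$p_nie <= 0.05
  report <- structure(list(step1 = step1, step2 = g, step3 = step3,
                           untested = untested,
                           config_hash = object_hash(strip_out(cfg))),
                      class = "replication_report")
  if (!is.null(cfg$out)) {
    dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
    write_table_prov(step1$results,
                     file.path(cfg$out, "replication_step1.tsv"),
                     report$config_hash)
    write_table_prov(g, file.path(cfg$out, "replication_step2.tsv"),
                     report$config_hash)
    write_table_prov(step3, file.path(cfg$out, "replication_step3.tsv"),
                     report$config_hash)
  }
  report
}
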