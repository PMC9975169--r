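#!/usr/bin/env Rscript
# Step 1 of the mapping procedure: epigenome-wide association of log10(TG).
#
# Kinship mixed model per probe (TG ~ probe + sex + age + 5 cell-type PCs
# [+ medication flags]), run twice: all participants with the
# lipid-medication flag as covariate, and the subset not on lipid-lowering
# medication. Correlated significant probes are reduced to representative
# loci by single-linkage clustering at |r| >= 0.8, and the joint variance
# in TG explained by the representatives is estimated with the multi-locus
# mixed model.

library(epimediate)

paths <- list(
  methylation = "results/cohort/methylation.tsv",
  annotation  = "results/cohort/annotation.tsv",
  phenotypes  = "results/cohort/phenotypes.tsv",
  exposures   = setNames(sprintf("results/cohort/exposures_exam%d.tsv", 5:8),
                         sprintf("exam%d", 5:8)),
  pedigree    = "results/cohort/pedigree.fam",
  truth       = "results/cohort/truth.tsv")
bundle <- load_bundle(paths)
bundle$methylation <- qc_filter_probes(bundle$methylation, bundle$annotation)
bundle <- add_cell_pcs(bundle, k = 5)

threshold <- 1.1e-7
ewas_all <- run_ewas(bundle, analysis_set = "All", threshold = threshold)
ewas_nomed <- run_ewas(bundle, analysis_set = "NoLipidMed",
                       threshold = threshold)

reps <- select_representative_loci(ewas_all, bundle$methylation, 0.8)
sel <- bundle$phenotypes$lipid_med == 0
mlv <- multilocus_variance(
  transform_tg(bundle$phenotypes$tg_mgdl)[sel],
  bundle$methylation[sel, reps, drop = FALSE],
  epimediate:::build_covariates(bundle, c("sex", "age"), "NoLipidMed")[sel, ],
  epimediate:::subset_kinship(bundle$kinship, sel))

dir.create("results/ewas", showWarnings = FALSE, recursive = TRUE)
write.table(ewas_all$results, "results/ewas/ewas_all.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(ewas_nomed$results, "results/ewas/ewas_nolipidmed.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
writeLines(reps, "results/ewas/representative_loci.txt")

cat(sprintf("significant probes at p <= %.2g: %d (All), %d (NoLipidMed)\n",
            threshold, length(ewas_all$significant_probes),
            length(ewas_nomed$significant_probes)))
cat(sprintf("representative loci after |r| >= 0.8 clustering: %d\n",
            length(reps)))
cat(sprintf("joint variance in TG explained by representatives: %.1f%%\n",
            mlv))
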