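#!/usr/bin/env Rscript
# Step 2: which dietary/lifestyle exposures track the TG-associated CpGs?
#
# For every representative locus, every exposure-panel variable is tested
# per exam in the kinship mixed model (methylation as the response).
# Because the ~300 panel variables are heavily correlated, the per-DMS
# Bonferroni correction divides alpha by the effective number of
# independent tests (eigenvalue method) of that exam's panel rather than by
# the raw variable count. Earlier-exam models keep age at the reference
# exam as a covariate since methylation was measured then.

library(epimediate)

paths <- list(
  methylation = "results/cohort/methylation.tsv",
  annotation  = "results/cohort/annotation.tsv",
  phenotypes  = "results/cohort/phenotypes.tsv",
  exposures   = setNames(sprintf("results/cohort/exposures_exam%d.tsv", 5:8),
                         sprintf("exam%d", 5:8)),
  pedigree    = "results/cohort/pedigree.fam")
bundle <- load_bundle(paths)
bundle$methylation <- qc_filter_probes(bundle$methylation, bundle$annotation)
bundle <- add_cell_pcs(bundle, k = 5)

reps <- readLines("results/ewas/representative_loci.txt")
grid <- map_exposures(bundle, reps, alpha = 0.05)
summary_tabs <- count_and_rank(grid)

dir.create("results/exposure_mapping", showWarnings = FALSE, recursive = TRUE)
write.table(grid$grid, "results/exposure_mapping/association_grid.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
write.table(data.frame(exam = names(grid$meff), meff = grid$meff,
                       threshold = grid$threshold),
            "results/exposure_mapping/meff.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
for (nm in names(summary_tabs))
  write.table(summary_tabs[[nm]],
              sprintf("results/exposure_mapping/%s.tsv", nm), sep = "\t",
              row.names = FALSE, quote = FALSE)

cat("effective number of tests per exam:\n")
print(round(grid$meff, 1))
cat("\ntop exposures by significant associations (No lipid med):\n")
rk <- summary_tabs$ranking
rk <- rk[rk$analysis_set == "NoLipidMed" & rk$n_associations > 0, ]
print(head(rk, 10), row.names = FALSE)
up <- summary_tabs$unique_pairs
cat(sprintf("\nunique significant (DMS, exposure) pairs: %s\n",
            paste(sprintf("%s=%d", up$analysis_set, up$unique_pairs),
                  collapse = ", ")))
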