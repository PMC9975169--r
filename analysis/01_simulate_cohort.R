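#!/usr/bin/env Rscript
# Step 0 of the workflow: generate the synthetic discovery cohort.
#
# The generator emulates a family-based methylation study: ~500 nuclear
# families (~2,000 individuals), 1,500 CpG probes mixed over six blood cell
# types, a 300-variable dietary/lifestyle panel observed at four exams
# (exam5..exam8), and planted exposure -> CpG -> log10(TG) mediation chains
# at 12 known TG-associated CpGs (alcohol hypomethylates most of them,
# carbohydrate acts in the opposite direction). The truth table written
# alongside the data is what later steps are judged against.

library(epimediate)

cfg <- sim_config(n_families = 500, n_probes = 1500, seed = 20260921)
bundle <- simulate_cohort(cfg, expression = TRUE)

dir.create("results", showWarnings = FALSE)
write_cohort(bundle, "results/cohort")

cat(sprintf("cohort: %d samples in %d families, %d probes, %d exams\n",
            nrow(bundle$phenotypes), length(unique(bundle$phenotypes$fam)),
            ncol(bundle$methylation), length(bundle$exposures)))
cat(sprintf("on lipid-lowering medication: %d (%.0f%%)\n",
            sum(bundle$phenotypes$lipid_med),
            100 * mean(bundle$phenotypes$lipid_med)))
cat(sprintf("median TG %.0f mg/dL; planted mediation chains: %d\n",
            median(bundle$phenotypes$tg_mgdl),
            sum(bundle$truth$alpha1 != 0)))
cat("written to results/cohort/\n")
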