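#!/usr/bin/env Rscript
# Simulate the two study cohorts and write them as delimited files with
# manifests, plus a Table-1-style characteristics table for each.
#
# Usage: Rscript analysis/01_simulate.R [seed]

library(brcaness)
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L

dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)

# Biobank-like training cohort: n = 1831, ~5.5% germline BRCA1/2 carriers,
# 179-miRNA serum panel + 19 binary clinical variables with realistic
# per-variable missingness.
train <- generate_training_cohort(synthetic_spec(seed = seed))
write_cohort(train, "results/cohorts/training")
cat(sprintf("training cohort: %d samples, %d carriers (%.1f%%)\n",
            length(train$sample_ids), sum(train$labels),
            100 * mean(train$labels)))

tab <- characteristics_table(train, by = "labels")
write.csv(tab, "results/tables/training_characteristics.csv", row.names = FALSE)
cat(sprintf("characteristics: %d/%d variables differ at p < 0.05 between carriers and non-carriers\n",
            sum(tab$p < 0.05, na.rm = TRUE), nrow(tab)))

# PLCO-like external cohort: n = 1044, 5-year ovarian-cancer outcome whose
# probability rises exponentially with a latent BRCAness-like score.
ext <- generate_external_cohort(synthetic_spec(n_samples = 1044, external = TRUE,
                                               seed = seed + 1L))
write_cohort(ext, "results/cohorts/external")
cat(sprintf("external cohort: %d samples, %d cancer cases (%.1f%%), blood drawn 1-1814 days before diagnosis\n",
            length(ext$sample_ids), sum(ext$cancer_outcome),
            100 * mean(ext$cancer_outcome)))

ext_tab <- characteristics_table(ext, by = "cancer_outcome")
write.csv(ext_tab, "results/tables/external_characteristics.csv", row.names = FALSE)
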