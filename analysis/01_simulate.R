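#!/usr/bin/env Rscript
# Step 1: simulate the field campaign.
#
# Four N treatments (0/50/100/150 kg/ha) in four replicated plots each,
# 22 leaf samples per plot: leaf N content per treatment and reflectance on
# the 401-1000 nm grid, plus the per-treatment yield table. Everything is
# seeded; downstream steps read the CSVs written here.

suppressPackageStartupMessages(library(nitrospec))
dir.create("results", showWarnings = FALSE)

cfg <- sim_config(seed = 20260929)
samples <- generate_samples(cfg)
yields <- generate_yields(cfg)

write_table_csv(samples, "results/samples.csv")
write_table_csv(yields, "results/yields.csv")

cat(sprintf("simulated %d leaf samples across %d plots\n",
            nrow(samples), length(unique(samples$plot_id))))
cat(sprintf("leaf N content: %.2f-%.2f mg/g, mean %.2f, sd %.2f\n",
            min(samples$n_content), max(samples$n_content),
            mean(samples$n_content), sd(samples$n_content)))
print(yields)
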