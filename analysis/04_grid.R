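#!/usr/bin/env Rscript
# Step 4: the 4 x 3 inversion grid.
#
# Every reduction (DWMD / SPA / PCA / IRIV) feeds every regressor
# (PLSR / ELM / GA-ELM) on identical train/validation splits; R-squared and
# RMSE (mg/g) are reported per cell. SPA start positions and the IRIV
# interval scan are run at reduced resolution here to keep the grid to a
# few minutes; 03_reduce.R performs the full-resolution selections.

suppressPackageStartupMessages(library(nitrospec))

cfg <- grid_config(
  seed = 20260929,
  reduce_options = list(
    spa = list(candidate_N = 2:8, k0_candidates = seq(1, 600, by = 10)),
    iriv = list(intervals = NULL, sipls_folds = 10)),
  model_options = list(elm = list(s2 = 20), gaelm = list(s2 = 20)))

grid <- run_grid(cfg)
write_table_csv(grid$reports, "results/grid_reports.csv")
print(grid)

best <- grid$reports[which.max(grid$reports$r2_val), ]
cat(sprintf("\nbest cell: %s x %s, validation R2 %.3f, RMSE %.3f mg/g\n",
            best$reduction, best$model, best$r2_val, best$rmse_val))
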