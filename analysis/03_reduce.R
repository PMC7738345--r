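#!/usr/bin/env Rscript
# Step 3: dimensionality reduction of the difference spectra.
#
# Four routes: (i) DWMD - multiscale wavelet decomposition, keeping the
# final approximation coefficients after selecting the mother wavelet and
# depth by the compression/correlation rule; (ii) SPA - successive
# projections band selection; (iii) PCA - five principal components;
# (iv) IRIV - synergy-interval PLS screening to a 4-interval joint region,
# iterative retention, and correlation pruning. All data-driven choices use
# the training split only. The full SPA start-position scan and the
# exhaustive 4-of-30 interval enumeration take a few minutes.

suppressPackageStartupMessages(library(nitrospec))

diffs <- read_difference_set("results/differences.csv")
tr <- split_side(diffs, "train")

# DWMD: selection report mirrors the compression study's table
sel <- select_wavelet_and_level(tr$X)
write_table_csv(sel$report, "results/wavelet_selection.csv")
cat(sprintf("DWMD: %s at level %d -> %d approximation coefficients\n",
            sel$spec$family, sel$spec$level,
            approx_length(600, sel$spec$filter_length, sel$spec$level)))

# SPA: scan every 5th start band, chains up to 10 bands
spa <- spa_select(tr$X, tr$y, candidate_N = 2:10,
                  k0_candidates = seq(1, 600, by = 5), folds = 10, seed = 31)
cat(sprintf("SPA: %d bands at %s nm (RMSECV %.3f mg/g)\n",
            length(spa$bands),
            paste(wavelength_grid()[spa$bands], collapse = ", "),
            spa$rmsecv))

# IRIV: full 4-of-30 interval enumeration, then retention and pruning
iriv <- iriv_select(tr$X, tr$y, seed = 32)
cat(sprintf("IRIV: joint intervals %s (%d combinations scanned)\n",
            paste(sort(iriv$joint$intervals), collapse = ", "),
            iriv$joint$n_combinations))
cat(sprintf("IRIV: %d bands retained after iteration, %d after pruning: %s nm\n",
            length(iriv$iriv$retained), length(iriv$bands),
            paste(wavelength_grid()[iriv$bands], collapse = ", ")))

bands <- rbind(
  data.frame(method = "spa", band = spa$bands,
             wavelength_nm = wavelength_grid()[spa$bands]),
  data.frame(method = "iriv", band = iriv$bands,
             wavelength_nm = wavelength_grid()[iriv$bands]))
write_table_csv(bands, "results/selected_bands.csv")
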