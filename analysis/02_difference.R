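#!/usr/bin/env Rscript
# Step 2: standard field and difference construction.
#
# The treatment with the highest yield becomes the standard field; its mean
# spectrum and mean leaf N define the reference. Every non-standard sample
# is expressed as a signed difference from that reference and the set is
# split 73/27 into training and validation.

suppressPackageStartupMessages(library(nitrospec))

samples <- read_table_csv("results/samples.csv")
yields <- read_table_csv("results/yields.csv")

standard <- select_standard(yields)
reference <- build_reference(samples, standard)
diffs <- compute_differences(samples, reference)
diffs <- split_train_validation(diffs, seed = 20260930)

write_difference_set(diffs, "results/differences.csv")

cat(sprintf("standard field: %g kg/ha (yield %.2f kg/667 m^2)\n",
            standard, max(yields$yield)))
cat(sprintf("standard N content: %.3f mg/g\n", reference$standard_n))
print(diffs)
cat(sprintf("N deficiency range: %.2f to %.2f mg/g\n",
            min(diffs$delta_n), max(diffs$delta_n)))
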