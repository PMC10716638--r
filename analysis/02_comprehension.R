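#!/usr/bin/env Rscript

# Step 2: comprehension-question accuracy, the attention check run before
# any eye-movement analysis. The study reports 99% correct; the simulated
# experiment plants a 1% error rate, so the estimate should land there.

library(gazediv)

design <- read_design("results/sim/design.csv")
acc <- comprehension_accuracy(design)

cat(sprintf("Overall comprehension accuracy: %.1f%% of %d trials\n",
            100 * acc$overall, nrow(design)))
cat(sprintf("Per-participant range: %.1f%% - %.1f%%\n",
            100 * min(acc$by_participant$accuracy),
            100 * max(acc$by_participant$accuracy)))

readr::write_csv(acc$by_participant, "results/comprehension.csv")
cat("Wrote results/comprehension.csv\n")
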