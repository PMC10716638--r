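#!/usr/bin/env Rscript

# Step 4: fixation time-course figures in the style of the study's plots --
# mean proportion curves with standard-error bands, a dashed 0.50 null
# line, and a dotted marker at the detected divergence point.

library(gazediv)

tab <- read_binned_table("results/sim/binned.csv")
report <- jsonlite::read_json("results/report.json")
dir.create("results/figures", showWarnings = FALSE)

panels <- list(
  egocentric_all = list("compatible_vs_incompatible", "all_gendered"),
  egocentric_mismatch = list("compatible_vs_incompatible", "gender_mismatch"),
  egocentric_match = list("compatible_vs_incompatible", "gender_match"),
  targets_gendered = list("targets_vs_distractors", "all_gendered"),
  targets_neutral = list("targets_vs_distractors", "neutral")
)

for (nm in names(panels)) {
  sel <- select_trials(tab, panels[[nm]][[2]])
  cv <- proportion_curves(sel, panels[[nm]][[1]])
  onset <- suppressWarnings(as.numeric(report$results[[nm]]$onset_ms))
  gg <- plot_curves(cv, onset_ms = if (length(onset) != 1) NA else onset)
  ggplot2::ggsave(file.path("results/figures", paste0(nm, ".pdf")),
                  gg, width = 7, height = 4.5)
  cat("Wrote results/figures/", nm, ".pdf\n", sep = "")
}
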