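#!/usr/bin/env Rscript

# Step 4: render the constancy-index reports (per-observer bars by skylight
# with the perfect-constancy line and across-skylight mean line) and print a
# compact text summary of the whole run.

suppressPackageStartupMessages(library(shadowconstancy))

dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)

for (preset in c("exp1", "exp2", "grey_paper_followup")) {
  ci <- read_ci_csv(file.path("results", preset, "ci.csv"))
  p <- ci_plot(ci)
  out <- file.path("results/figures", paste0("ci_", preset, ".pdf"))
  n_obs <- length(unique(ci$observer))
  ggplot2::ggsave(out, p, width = 2 + 2 * n_obs, height = 6, limitsize = FALSE)
  cat(sprintf("%-20s mean CI %.3f (range %.2f to %.2f) -> %s\n",
              preset, mean(ci$ci), min(ci$ci), max(ci$ci), out))
}

cat("\nInterpretation guide: CI = 0 no constancy, 1 perfect, > 1\n")
cat("over-correction of the skylight color; negative values indicate\n")
cat("settings shifted against the illuminant change.\n")
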