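#!/usr/bin/env Rscript

# Step 2: simulate achromatic settings for the three scenario presets.
# The main experiment (exp1: 3 practiced observers, two lighting blocks,
# 7 sessions), the larger outlined-shadow design (exp2: 12 observers, two
# outline blocks, 2 sessions), and the grey-paper follow-up in which
# constancy collapses to near zero.

suppressPackageStartupMessages(library(shadowconstancy))

scene <- scene_illuminants(seed = 1L)

for (preset in c("exp1", "exp2", "grey_paper_followup")) {
  cfg <- scenario_preset(preset)
  cfg$seed <- 2024L
  out_dir <- file.path("results", preset)
  simulate_to_csv(cfg, out_dir, scene = scene)
  write_config_yaml(cfg, file.path(out_dir, "config.yaml"))
  n <- nrow(read_settings_csv(file.path(out_dir, "settings.csv")))
  cat(sprintf("%-20s %4d settings rows -> %s/settings.csv\n", preset, n, out_dir))
}
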