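#!/usr/bin/env Rscript
# Step 1: simulate the study cohorts.
#
# Three cross-sectional label-propagation cohorts are generated from one
# shared set of stem-cell kinetics, differing only in how strongly each
# Cre-driver-like design labels the two hidden HSC subcompartments
# (21:1, 4:1 and 30:1 HSC-U:HSC-D), plus the two-label toy pair used to
# illustrate that labeling differences alone reshape the normalized
# curves. Tables and the generating truth go to results/synthetic/.

suppressPackageStartupMessages(library(hscflux))

seed <- 20260401
out_dir <- "results/synthetic"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

rates <- default_rates()
n0 <- default_initial_counts()
designs <- list("tie2-like", "fgd5-like", "krt18-like", "toy-I", "toy-J")

cohorts <- generate_multi_dataset(rates, n0, designs, seed = seed)
for (nm in names(cohorts)) {
  path <- file.path(out_dir, paste0(nm, ".tsv"))
  write_observations(cohorts[[nm]], path)
  cat(sprintf("%-11s %4d mice  -> %s\n", nm,
              length(unique(cohorts[[nm]]$mouse_id)), path))
}
write_truth_manifest(rates, n0, designs,
                     file.path(out_dir, "truth_manifest.json"))
model_config_write(rates, n0,
                   f0 = lapply(setNames(designs[1:3], unlist(designs[1:3])),
                               function(d) preset_designs(d)$f0),
                   path = file.path(out_dir, "model_config.json"))
cat("truth manifest and model config written\n")
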