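#!/usr/bin/env Rscript
# Stage 1 — simulate a study with the layout of the real one.
#
# Builds a synthetic bundle that mirrors the study design: 12 CNS
# case-control comparisons (5 familial, 7 sporadic, with the real cohort
# sizes) plus 4 diMN comparisons (transcriptomic and proteomic, per
# subtype), over 2000 genes. Ten targets are planted at log2 effect 1.5 with
# full penetrance, and five pathways are planted with a coherent activation
# shift of 0.05 so later stages have a recoverable truth. Everything
# downstream reads only the files written here.

library(alstargets)

seed <- as.integer(Sys.getenv("ALS_SEED", "1"))
out <- "results/analysis"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

planted <- sprintf("G%05d", seq(10, 100, by = 10))
cfg <- study_config(
  design = default_study_design(),
  n_genes = 2000,
  planted_targets = data.frame(gene = planted,
                               direction = rep(c("up", "down"), 5),
                               effect_size = 1.5, penetrance = 1),
  planted_pathways = data.frame(pathway = sprintf("PW%04d", 1:5),
                                direction = c("up", "up", "down", "up",
                                              "down"),
                                magnitude = 0.05),
  seed = seed)
bundle <- generate_study(cfg)
saveRDS(bundle, file.path("results", "bundle.rds"))  # scratch hand-off only

print(bundle)
cat("Planted targets:", paste(planted, collapse = " "), "\n")
cat("Planted pathways: PW0001..PW0005 (3 up, 2 down)\n")
write.table(bundle$chronology, file.path(out, "chronology.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("Chronology written for the time-machine stage;",
    sum(bundle$chronology$year > cfg$chronology_cutoff),
    "genes enter trials after", cfg$chronology_cutoff, "\n")
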