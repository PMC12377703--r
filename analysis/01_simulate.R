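#!/usr/bin/env Rscript
# Step 1 -- generate the study dataset.
#
# The public FAERS download is multi-gigabyte and versioned against a
# licensed MedDRA dictionary, so this workflow runs on the bundled
# synthetic scenario: 40,000 cases across 2004Q1-2024Q2 with four strong
# injected pulmonary-edema signals, several weaker ones, one
# age-confounded null drug, and known onset distributions.  The written
# files use the FAERS quarterly ASCII layout, so pointing the later steps
# at a real FAERS extract is a drop-in change.

library(dipesignal)

seed <- 20240731 %% 10000
dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)
sim_dir <- "scratch/simulated_faers"

cfg <- paper_shaped_scenario(n_reports = 40000, seed = seed)
g <- generate_faers(cfg, sim_dir)

cat("wrote", length(g$files), "quarterly files to", sim_dir, "\n")
cat("ground truth:", sum(g$manifest$true_or > 1), "drugs with injected",
    "effects;", sum(g$manifest$confounded), "confounded null\n")
cat("manifest at", file.path(sim_dir, "manifest.tsv"), "\n")
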