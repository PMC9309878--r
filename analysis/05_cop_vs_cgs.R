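#!/usr/bin/env Rscript
# Step 5: pedigree- vs marker-based relatedness. Mantel correlation between
# the COP and CGS matrices of the simulated program and their joint
# class-frequency table (both x100, zero class separated).

suppressPackageStartupMessages(library(germtrace))
seed <- if (length(commandArgs(TRUE))) as.integer(commandArgs(TRUE)[[1]]) else 1L

run_report(list(pedigree = "results/sim_pedigree.tsv",
                vcf = "results/sim_genotypes.vcf",
                out_dir = "results", seed = seed, n_perm = 999L),
           "compare")

mt <- read.delim("results/compare_mantel.tsv", comment.char = "#")
cat("COP vs CGS comparison:\n")
print(mt)
means <- read.delim("results/compare_means.tsv", comment.char = "#")
print(means)
cat("\nJoint COP x CGS class counts written to",
    "results/compare_joint_bins.tsv\n")
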