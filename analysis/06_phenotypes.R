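#!/usr/bin/env Rscript
# Step 6: multi-environment phenotype analysis on a simulated trial laid out
# like the field design (two environments, blocks within environments):
# RCBD ANOVA, variance components from expected mean squares, and the
# genetic coefficient of variation.

suppressPackageStartupMessages(library(germtrace))
seed <- if (length(commandArgs(TRUE))) as.integer(commandArgs(TRUE)[[1]]) else 1L

reg <- read.delim("results/sim_regions.tsv", comment.char = "#")
set.seed(seed + 60L)
ids <- reg$id
ng <- length(ids)
# genotype values with a 12% genetic coefficient of variation around 100 d
gval <- rnorm(ng, 0, 12)
d <- expand.grid(genotype = ids, environment = c("E1", "E2"),
                 block = c("B1", "B2", "B3"), stringsAsFactors = FALSE)
gi <- match(d$genotype, ids)
d$trait <- "days_to_maturity"
d$value <- 100 + c(-3, 3)[match(d$environment, c("E1", "E2"))] +
  gval[gi] + rnorm(nrow(d), 0, 5)

run_report(list(trial = d, out_dir = "results", seed = seed), "anova")
an <- read.delim("results/anova_gcv.tsv", comment.char = "#")
cat("RCBD ANOVA with variance components:\n")
print(an)

means <- tapply(d$value, d$genotype, mean)
s <- subpopulation_summary(setNames(as.numeric(means), names(means)),
                           setNames(reg$region, reg$id))
write.table(s, "results/trait_by_region.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("\nTrait summary by ecoregion:\n")
print(s)
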