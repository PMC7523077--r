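#!/usr/bin/env Rscript
# Stage 1: generate the benchmark dataset the downstream stages analyze.
#
# Two conditions (vehicle control vs. combined drug treatment), 10 samples
# each, 32 metabolites in four coordinately regulated blocks of 8; block B1
# drives the phenotype trait (tumor volume analogue) and loses its latent
# coupling under treatment. Writes the abundance table, sample metadata,
# metabolite->pathway map and the planted ground truth.

suppressMessages(library(metconnect))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L

spec <- synthetic_spec(n_samples_per_condition = 10, n_metabolites = 32,
                       seed = seed)
paths <- write_dataset(spec, "results/data")

tt <- truth_table(spec)
cat("simulated", spec$n_metabolites, "metabolites x",
    2 * spec$n_samples_per_condition, "samples (seed ", seed, ")\n")
cat("planted edges: control", nrow(tt$edges$control),
    "| treated", nrow(tt$edges$treated),
    "(block", spec$treatment_disrupted_blocks, "disrupted)\n")
cat("wrote:", paste(basename(paths), collapse = ", "), "-> results/data\n")
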