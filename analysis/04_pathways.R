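#!/usr/bin/env Rscript
# Stage 4: pathway eigenmetabolites, pathway-pathway connectivity per
# condition, the control-vs-treated contrast, and the Circos table export
# of network edges counted by pathway pair.

suppressMessages(library(metconnect))

am <- read_abundance("results/data/abundance.tsv",
                     meta = "results/data/metadata.tsv")
map <- read_pathway_map("results/data/pathway_map.tsv")
members <- suppressWarnings(pathway_members(map, colnames(am$values)))
dir.create("results/pathways", showWarnings = FALSE, recursive = TRUE)

pcs <- list()
for (cond in c("control", "treated")) {
  profs <- suppressWarnings(pathway_eigenmetabolites(am, cond, members))
  ve <- vapply(profs, `[[`, numeric(1), "variance_explained")
  cat(cond, ": eigenmetabolites for", length(profs),
      "pathways; median variance explained",
      sprintf("%.2f", median(ve)), "\n")
  pcs[[cond]] <- pathway_correlation(profs)
  write.table(format(pcs[[cond]]$rho, digits = 15, trim = TRUE),
              sprintf("results/pathways/pathway_rho_%s.tsv", cond),
              sep = "\t", quote = FALSE)
}

cc <- condition_contrast(pcs$control, pcs$treated)
write.table(cc, "results/pathways/pathway_contrast.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("disrupted pathways:",
    paste(cc$pathway[cc$disrupted], collapse = ", "), "\n")

net <- read_network("results/networks/network_control.tsv", "control")
counts <- pathway_edge_counts(net, members)
write_circos_table(counts, "results/pathways/circos_control.txt")
cat("circos table:", nrow(counts), "pathways,",
    sum(counts[upper.tri(counts, diag = TRUE)]), "edges\n")
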