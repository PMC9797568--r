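#!/usr/bin/env Rscript
# Identify per-cluster hub genes (top-3 in at least 3 of the 4 centrality
# metrics) and label each selected cluster with its most significant
# covering functional term.

suppressPackageStartupMessages(library(coumnet))

edges <- read_edges("results/data/ppi_edges.tsv")
degs <- filter_degs(read_degs("results/data/degs.tsv"))
assign <- read.delim("results/cluster_assignments.tsv")
selected <- as.integer(readLines("results/selected_clusters.txt"))
terms <- read_gmt("results/data/terms.gmt")

graph <- build_enhanced_graph(edges, degs)
membership <- setNames(assign$cluster, assign$gene)

cent <- centralities(graph, membership)
hubs <- select_hubs(cent)
cat(sprintf("%d hub genes across %d clusters:\n", nrow(hubs),
            length(unique(hubs$cluster))))
print(hubs)

universe <- read_degs("results/data/degs.tsv")$gene
enr_all <- lapply(selected, function(cl) {
  res <- enrich_terms(assign$gene[assign$cluster == cl], universe, terms)
  res$cluster <- cl
  res
})
enr <- do.call(rbind, enr_all)
labels <- vapply(enr_all, label_cluster, "")
cat("Cluster labels (lowest-FDR term covering >= 50% of the cluster):\n")
for (i in seq_along(selected)) {
  cat(sprintf("  C%d -> %s\n", selected[i], labels[i]))
}

write.table(cent, "results/centralities.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(hubs, "results/hubs.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(enr, "results/enrichment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
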