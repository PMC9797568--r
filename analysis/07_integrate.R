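#!/usr/bin/env Rscript
# Assemble the signed, directed multi-omics network
# (variant -> gene -> pathway/phenotype), restrict it to the hub-anchored
# sub-network, and tabulate the final gene-level model.

suppressPackageStartupMessages(library(coumnet))

degs <- filter_degs(read_degs("results/data/degs.tsv"))
assign <- read.delim("results/cluster_assignments.tsv")
hubs <- read.delim("results/hubs.tsv")
assoc <- read.delim("results/associations.tsv")
classified <- read.delim("results/variants_classified.tsv")
terms <- read_gmt("results/data/terms.gmt")
pert <- read.csv("results/data/perturbations.csv")

memberships <- do.call(rbind, lapply(names(terms), function(tn) {
  data.frame(gene = terms[[tn]], pathway = tn)
}))
genes <- data.frame(gene = degs$gene, log2FC = degs$log2FC,
                    cluster = assign$cluster[match(degs$gene, assign$gene)])

# phenotype change directions from the physiology comparisons:
# ethanol production rate up, biomass yield down under stress
dirs <- c(qEthanol = "up", biomass_yield = "down")

network <- assemble(genes, memberships, pert, assoc, classified,
                    phenotype_directions = dirs)
anchored <- extract_anchor_subnetwork(network, hubs$gene)
model <- tabulate_model(anchored)

cat(sprintf("Full network: %d nodes, %d edges.\n", nrow(network$nodes),
            nrow(network$edges)))
cat(sprintf("Hub-anchored model: %d genes, %d positive and %d negative interactions.\n",
            nrow(model$table), model$n_positive, model$n_negative))
print(model$table[, c("gene", "cluster", "phenotype_links", "has_variant")])

igraph::write_graph(integration_igraph(network),
                    "results/integration_network.graphml",
                    format = "graphml")
jsonlite::write_json(
  list(nodes = anchored$nodes, edges = anchored$edges),
  "results/anchored_network.json", auto_unbox = TRUE, digits = NA)
write.table(model$table, "results/model_table.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
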