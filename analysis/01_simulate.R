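#!/usr/bin/env Rscript
# Generate the synthetic study: a planted-community interaction graph with
# cluster-correlated fold changes, per-sample expression driving two
# physiological phenotypes, and variant calls spanning every zygosity and
# impact class. All downstream steps read these files.

suppressPackageStartupMessages(library(coumnet))

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

spec <- synthetic_spec(seed = 7)
study <- generate_study(spec)

write_edges(study$edges, file.path(out, "ppi_edges.tsv"))
write_degs(study$degs, file.path(out, "degs.tsv"))
write_expression(study$expression, file.path(out, "expression.tsv"))
write_phenotypes(study$phenotypes, file.path(out, "phenotypes.csv"))
write_vcf(study$vcf, file.path(out, "variants.vcf"))
write_consequences(study$consequences, file.path(out, "consequences.tsv"))
write_gmt(study$terms, file.path(out, "terms.gmt"))
write.csv(study$perturbations, file.path(out, "perturbations.csv"),
          row.names = FALSE, quote = FALSE)
write.table(data.frame(gene = names(study$truth$clusters),
                       cluster = study$truth$clusters),
            file.path(out, "ground_truth_clusters.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf(
  "Simulated %d genes in %d clusters, %d interactions, %d samples, %d variants.\n",
  nrow(study$degs), spec$n_clusters, nrow(study$edges),
  spec$n_samples, nrow(study$vcf)))
cat("Inputs written under", out, "\n")
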