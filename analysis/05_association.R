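#!/usr/bin/env Rscript
# Associate every gene with the measured phenotypes: Sturges-rule
# discretization, Dirichlet-multinomial evidence comparison, sign from the
# continuous-value correlation.

suppressPackageStartupMessages(library(coumnet))

expr <- read_expression("results/data/expression.tsv")
pheno <- read_phenotypes("results/data/phenotypes.csv")

assoc <- associate_all(expr, pheno)
write.table(assoc, "results/associations.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

passing <- assoc[assoc$passes, ]
cat(sprintf("%d of %d gene-phenotype pairs pass (evidence gain > 0).\n",
            nrow(passing), nrow(assoc)))
for (ph in unique(passing$phenotype)) {
  sub <- passing[passing$phenotype == ph, ]
  cat(sprintf("  %-14s %3d genes (%d positive, %d negative)\n", ph,
              nrow(sub), sum(sub$sign == "+"), sum(sub$sign == "-")))
}
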