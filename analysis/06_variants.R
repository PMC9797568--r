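#!/usr/bin/env Rscript
# Classify short variants by zygosity (homozygous / heterozygous with or
# without reference) and predicted impact tier, and summarize the classes.

suppressPackageStartupMessages(library(coumnet))

vcf <- read_vcf("results/data/variants.vcf")
cons <- read_consequences("results/data/consequences.tsv")

classified <- classify_variants(vcf, cons)
s <- summarize_variants(classified)

cat("Zygosity x impact tier counts ((variant, gene) rows):\n")
print(s$by_class)
cat(sprintf("%d distinct variants over %d annotation rows", s$n_variants,
            s$n_rows))
cat(" (a variant can impact more than one gene).\n")

write.table(classified, "results/variants_classified.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(as.data.frame(s$by_class), "results/variant_summary.tsv",
            sep = "\t", quote = FALSE)
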