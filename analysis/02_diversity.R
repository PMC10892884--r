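#!/usr/bin/env Rscript
# Stage 2: within-population diversity. Per-primer band/polymorphism counts,
# then Na, Ne, He, Is and %polymorphic per analyzable geographic group and
# for the pooled collection.

library(issrpop)

m <- read_band_matrix("results/data/band_matrix.csv")

primer <- per_primer_polymorphism(m)
write.table(primer, "results/primer_polymorphism.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
tot <- primer[primer$primer == "Total", ]
cat(sprintf("%d bands from %d primers, %d polymorphic (%.2f%%)\n",
            tot$bands, nrow(primer) - 1L, tot$polymorphic, tot$percent))

div <- rbind(diversity_summary(m, "population"),
             diversity_summary(m, "pooled"))
write.table(div, "results/diversity.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
pooled <- div[div$group == "pooled", ]
cat(sprintf("pooled diversity over %d loci: Ne = %.4f, He = %.4f, Is = %.4f\n",
            pooled$n_loci, pooled$Ne, pooled$He, pooled$Is))
cat(sprintf("%d analyzable groups; singleton groups excluded\n",
            nrow(div) - 1L))
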