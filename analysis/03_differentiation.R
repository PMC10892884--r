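#!/usr/bin/env Rscript
# Stage 3: partition of gene diversity into within- and among-group
# components (HT, HS), the differentiation coefficient GST, and gene flow Nm
# under the haploid coefficient.

library(issrpop)

m <- read_band_matrix("results/data/band_matrix.csv")
ds <- differentiation_summary(m, nm_coefficient = 0.5)
print(ds)

tab <- data.frame(
  statistic = c("mean_HT", "sd_HT", "mean_HS", "sd_HS", "GST", "Nm",
                "percent_among", "percent_within"),
  value = c(ds$mean_HT, ds$sd_HT, ds$mean_HS, ds$sd_HS, ds$GST, ds$Nm,
            ds$percent_among, ds$percent_within))
write.table(tab, "results/differentiation.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(ds$per_locus, "results/differentiation_per_locus.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# worked-example cross-check against the published across-locus means
ref <- reference_table("diversity_partition")
g_pub <- gst(ref$value[ref$statistic == "mean_HT"],
             ref$value[ref$statistic == "mean_HS"])
cat(sprintf("published means give GST = %.4f, Nm = %.4f\n",
            g_pub, gene_flow(ref$value[ref$statistic == "GST"], 0.5)$Nm))
cat("note: with 2-8 isolates per group the estimated GST sits well above the\n",
    "generating F (sampling noise inflates the among-group variance); the\n",
    "parameter-recovery tests use n = 50 per group, where the bias is small\n",
    sep = "")
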