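#!/usr/bin/env Rscript
# Stage 5: virulence analysis of the simulated daily mortality records —
# per-strain mortality/mycosis means with standard errors, probit-on-log-time
# regression with LT50, and the Kaplan-Meier median lethal time.

library(issrpop)

rec <- read_bioassay("results/data/bioassay_records.csv")
tab <- bioassay_table(rec)
write.table(tab, "results/bioassay.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("%d strains analysed\n", nrow(tab)))
cat(sprintf("%d strains at 100%% mean mortality; minimum mean mortality %.1f%%\n",
            sum(tab$mortality == 100), min(tab$mortality)))
est <- !is.na(tab$lt50_probit)
cat(sprintf("LT50 estimable for %d strains; probit LT50 range %.2f-%.2f d\n",
            sum(est), min(tab$lt50_probit[est]), max(tab$lt50_probit[est])))
fast <- tab$strain[est][tab$lt50_probit[est] < 4]
if (length(fast) > 0)
  cat("strains with LT50 < 4 d:", paste(fast, collapse = ", "), "\n")
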