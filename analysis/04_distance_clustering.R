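#!/usr/bin/env Rscript
# Stage 4: Nei genetic identity/distance between geographic groups, the
# population-level UPGMA tree, and the individual-level Dice-similarity tree
# over all 31 isolates, both serialized as Newick.

library(issrpop)

m <- read_band_matrix("results/data/band_matrix.csv")

idm <- identity_distance_matrix(m)
comb <- idm$distance
comb[upper.tri(comb)] <- idm$identity[upper.tri(comb)]
diag(comb) <- NA
write.csv(round(comb, 4), "results/identity_distance.csv", na = "")
off <- upper.tri(idm$identity)
cat(sprintf("identity range %.4f-%.4f; distance range %.4f-%.4f\n",
            min(idm$identity[off]), max(idm$identity[off]),
            min(idm$distance[off]), max(idm$distance[off])))

pop_tree <- upgma(idm$distance)
writeLines(to_newick(pop_tree), "results/population_upgma.nwk")

S <- individual_similarity(m, "dice")
write.csv(round(S, 4), "results/individual_similarity.csv")
ind_tree <- upgma(1 - S)
writeLines(to_newick(ind_tree), "results/individual_upgma.nwk")
cat(sprintf("individual UPGMA tree over %d isolates -> results/individual_upgma.nwk\n",
            length(ind_tree$labels)))
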