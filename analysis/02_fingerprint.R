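#!/usr/bin/env Rscript
# Stage 2: fingerprint similarity, UPGMA dendrogram, strain deduplication.
#
# Pairwise genomic similarity is the Pearson correlation of the
# Gaussian-smoothed densitometric curves (band-matching tolerance 0.5% of
# the log-size span, shift optimization 0.5%), after eliminating bands
# outside [300, 5000] bp. Strains above 90% similarity collapse to one
# representative (single linkage).

suppressMessages(library(colisurf))

profiles <- read_profiles("results/cohort/profiles.csv")
S <- similarity_matrix(profiles)
utils::write.csv(as.data.frame(unclass(S)), "results/similarity.csv")

strains <- utils::read.csv("results/cohort/strains.csv")
habitat <- strains$habitat[match(rownames(S), strains$strain_id)]
ut <- upper.tri(S)
same <- outer(habitat, habitat, "==")
message(sprintf("mean similarity within habitat %.3f, between habitats %.3f",
                mean(S[ut & same]), mean(S[ut & !same])))

tree <- ape::as.phylo(upgma(S))
ape::write.tree(tree, "results/dendrogram.nwk")

sel <- select_distinct(S, threshold = 0.90)
writeLines(sel$representatives, "results/representatives.txt")
message(sprintf("%d of %d strains genomically distinct at the 90%% criterion",
                length(sel$representatives), nrow(S)))
message("wrote results/similarity.csv, results/dendrogram.nwk, results/representatives.txt")
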