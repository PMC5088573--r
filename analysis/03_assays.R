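#!/usr/bin/env Rscript
# Stage 3: raw assay readings -> the eight surface properties per strain.
#
# MATH optical densities give hydrophobic partitioning; sample-vs-blank
# titration balances give the net charge profile, the charge at pH 8, the
# total acidity (charge at pH 4 minus pH 10) and the point of zero charge;
# Lowry / phenol-sulfuric absorbances invert their standard curves to EPS
# protein and sugar per 1e8 cells; zeta potential passes through from the
# instrument. Phylotypes come from the quadruplex marker lookup. Only
# representatives retained in stage 2 are kept.

suppressMessages(library(colisurf))

cohort <- read_cohort("results/cohort")
tab <- build_property_table(cohort)
tab$phylotype <- vapply(seq_len(nrow(cohort$strains)), function(i) {
  s <- cohort$strains[i, ]
  assign_phylotype(marker_profile(s$arpA, s$chuA, s$yjaA, s$tspE4,
                                  s$group_c, s$group_e))
}, character(1))

reps <- readLines("results/representatives.txt")
tab <- tab[tab$strain_id %in% reps, ]
utils::write.csv(tab, "results/properties.csv", row.names = FALSE)

message(sprintf("%d strains assayed; property ranges:", nrow(tab)))
for (p in property_names()) {
  message(sprintf("  %-15s %8.3g .. %8.3g", p,
                  min(tab[[p]], na.rm = TRUE), max(tab[[p]], na.rm = TRUE)))
}
message(sprintf("phylotype counts: %s",
                paste(names(table(tab$phylotype)), table(tab$phylotype),
                      sep = "=", collapse = ", ")))
message("wrote results/properties.csv")
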