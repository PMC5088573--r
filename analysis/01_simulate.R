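#!/usr/bin/env Rscript
# Stage 1: generate the study-scale synthetic cohort.
#
# 44 sediment + 33 water strains with habitat-structured fingerprints
# (shared band pool fraction 0.8), sediment-elevated hydrophobicity and EPS,
# less negative net charge and slightly lower acidity in sediment; all
# latent values recorded in truth.json. Writes the raw-data CSV layout that
# the later stages (and any real data set) use.

suppressMessages(library(colisurf))

seed <- 20260923L %% 2147483647L
cfg <- cohort_config(seed = seed)
cohort <- generate_cohort(cfg)
write_cohort(cohort, "results/cohort")

tr <- cohort$truth
message(sprintf("cohort: %d sediment + %d water strains (seed %d)",
                cfg$n_sediment, cfg$n_water, seed))
message(sprintf("true hydrophobicity: sediment mean %.3f, water mean %.3f",
                mean(tr$hydrophobicity[tr$habitat == "sediment"]),
                mean(tr$hydrophobicity[tr$habitat == "water"])))
message(sprintf("true net charge at pH 8 (meq/1e8 cells): sediment %.2e, water %.2e",
                mean(tr$net_charge_ph8[tr$habitat == "sediment"]),
                mean(tr$net_charge_ph8[tr$habitat == "water"])))
message("wrote results/cohort/{strains,profiles,titrations,blank,standards_*}.csv + truth.json")
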