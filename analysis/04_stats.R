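#!/usr/bin/env Rscript
# Stage 4: the inferential layer.
#
# Per property: boxplot five-number summaries by habitat, the rank-sum
# habitat comparison, and the relatedness-adjusted GLS habitat test (the
# repaired similarity matrix as residual covariance). Plus the Kendall
# tau-b correlation matrices (all / sediment / water strains), the Mantel
# test of similarity against habitat co-membership, and the
# hydrophobicity-vs-EPS-protein analysis within each habitat.

suppressMessages(library(colisurf))

tab <- utils::read.csv("results/properties.csv")
S <- as.matrix(utils::read.csv("results/similarity.csv", row.names = 1,
                               check.names = FALSE))
S <- S[tab$strain_id, tab$strain_id]

report <- habitat_report(tab, S, n_perm = 9999, seed = 20260923L)

jsonlite::write_json(colisurf:::flatten_report(report), "results/report.json",
                     digits = NA, auto_unbox = TRUE, pretty = TRUE,
                     na = "null")
utils::write.csv(as.data.frame(report$correlations$all$tau),
                 "results/table1.csv")

message(sprintf("Mantel: r = %.3f, p = %.2g  (similarity larger within habitat)",
                report$mantel$statistic, report$mantel$p_value))
message("per-property habitat comparison (sediment vs water):")
for (p in names(report$properties)) {
  r <- report$properties[[p]]
  if (is.null(r)) next
  message(sprintf("  %-15s rank-sum p = %8.2g   GLS beta = %9.3g, p = %8.2g",
                  p, r$wilcoxon$p_value, unname(r$pgls$beta[2]),
                  unname(r$pgls$p[2])))
}
k <- report$hydrophobicity_eps_protein
message(sprintf("hydrophobicity ~ EPS protein: sediment tau = %.3f (p = %.2g), water tau = %.3f (p = %.2g)",
                k$sediment$statistic, k$sediment$p_value,
                k$water$statistic, k$water$p_value))
message("wrote results/report.json, results/table1.csv")
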