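# colisurf

Habitat analysis of *E. coli* cell-surface properties with
fingerprint-based genomic relatedness.

## What this is for

Stream *E. coli* lives both suspended in the water column and attached to
bottom sediments. Strains isolated from the two habitats can differ in the
cell-surface properties that govern attachment and transport —
hydrophobicity, zeta potential, titratable surface charge, extracellular
polymeric substances (EPS) — but strains also differ in genome, and
related strains have related surfaces. `colisurf` implements the full
analysis chain for separating the two influences, for microbial ecologists
and water-quality modelers working with strain collections:

1. **Fingerprinting** — pairwise genomic similarity from (GTG)₅ rep-PCR
   band profiles as the shift-optimized Pearson correlation of
   Gaussian-smoothed densitometric curves (band filter [300, 5000] bp,
   matching tolerance and shift optimization both 0.5% of the log-size
   span); UPGMA dendrograms; deduplication at the 90% similarity
   criterion; revised-Clermont quadruplex phylotyping.
2. **Assays** — raw readings to eight properties per strain:
   MATH hydrophobic partitioning `(OD₀ − OD_aq)/OD₀`; zeta potential
   (pass-through); the net-charge profile from sample-vs-blank titration
   balances `[(C_A − C_B − [H⁺] + [OH⁻])_s − (·)_b]/N_bact × 10⁻³`
   (meq per 10⁸ cells); net charge at pH 8.0; total acidity
   (charge at pH 4 − charge at pH 10); point of zero charge; EPS protein
   and sugar through Lowry/phenol–sulfuric standard curves; their ratio.
3. **Inference** — Wilcoxon rank-sum habitat comparisons; Kendall tau-b
   correlation matrices (all / per habitat); a Mantel permutation test of
   similarity against habitat co-membership (positive r ⟺ similarity
   larger within habitat); and generalized least squares with the repaired
   similarity matrix as residual covariance
   (`y = β₀ + β₁·1{sediment} + e`, `Var(e) = σ²V`), which estimates the
   habitat effect net of genomic relatedness.
4. **Synthetic cohorts** — a generator with known ground truth
   (habitat-structured band pools, genome-correlated traits
   `y = μ + β·1{sediment} + g + ε` with `g ~ MVN(0, σ_g²V)`, titration
   curves from a multi-site Henderson–Hasselbalch model) for calibrating
   every stage without raw data.

The methods vignette (`vignettes/habitat-surface-analysis.Rmd`) documents
the model, parameter defaults, numerical choices and limitations.

## Worked example

The `analysis/` scripts run the workflow at study scale (44 sediment + 33
water strains) stage by stage, writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R     # synthetic cohort with known truth
Rscript analysis/02_fingerprint.R  # similarity, dendrogram, deduplication
Rscript analysis/03_assays.R       # eight properties per strain
Rscript analysis/04_stats.R        # comparisons, correlations, Mantel, GLS
Rscript analysis/05_calibration.R  # type-I error and effect recovery
```

A run prints (stage 2, 4 and 5 excerpts):

```
mean similarity within habitat 0.560, between habitats 0.493
76 of 77 strains genomically distinct at the 90% criterion

Mantel: r = 0.238, p = 1e-04  (similarity larger within habitat)
per-property habitat comparison (sediment vs water):
  hydrophobicity  rank-sum p =  3.2e-07   GLS beta =      0.13, p =  0.00024
  zeta_potential  rank-sum p =     0.82   GLS beta =     -2.07, p =     0.11
  eps_protein     rank-sum p =  7.1e-11   GLS beta =      0.11, p =  3.7e-08
  net_charge_ph8  rank-sum p =  5.5e-05   GLS beta =   3.6e-05, p =  0.00022

                  quantity      value   n
1        mantel_type1_rate      0.075 200
2          pgls_type1_rate      0.040 200
3 pgls_recovered_beta_mean      0.199 200
4   pgls_recovered_beta_sd      0.033 200
5         pgls_ci_coverage      0.965 200
```

Reading it: within-habitat fingerprint similarity exceeds between-habitat
similarity (positive Mantel r, permutation p ≈ 1e-4); one strain pair
exceeds the 90% criterion and collapses to one representative; sediment
strains have higher hydrophobicity and EPS and less negative net charge at
pH 8 (rank-sum p-values), and the habitat effect on hydrophobicity
survives discounting genomic relatedness (GLS habitat coefficient 0.13
against the generator's true effect 0.15, p ≈ 2e-4), while zeta potential —
generated with no habitat effect — shows none. The calibration stage
checks that the two habitat tests hold their nominal 5% size on null
cohorts (the printed rates carry Monte-Carlo noise of about ±0.03 at 200
cohorts) and that the GLS recovers a known effect of 0.2 without bias at
~95% CI coverage.

The same chain runs in-process via `run_all(run_config(...))`, or
`run_demo()` for a one-minute 12 + 12 cohort.

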