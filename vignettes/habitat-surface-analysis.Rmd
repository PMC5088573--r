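---
title: "Comparing E. coli surface properties between stream habitats with fingerprint-based relatedness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing E. coli surface properties between stream habitats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colisurf)
```

## The scientific question

*E. coli* in streams lives in two connected habitats: suspended in the
water column and associated with bottom sediments. Whether strains from the
two habitats differ systematically in cell-surface properties —
hydrophobicity, surface charge, extracellular polymeric substances (EPS) —
matters for fate-and-transport modelling of the organism as a fecal
indicator. The statistical difficulty is that strains are not independent
observations: genomically similar strains tend to have similar surfaces, so
a naive two-group comparison can mistake shared ancestry for a habitat
effect. `colisurf` implements the full chain from raw assay readings to a
habitat inference that discounts genomic relatedness, plus a
synthetic-cohort generator with known ground truth so every stage can be
calibrated.

## Fingerprint similarity and deduplication

Genomic relatedness is measured from (GTG)~5~ rep-PCR fingerprints. A
fingerprint enters as a *band profile* — fragment sizes in bp with
densitometric intensities — already ladder-normalized; gel-image processing
is out of scope. Bands outside [300, 5000] bp are eliminated before
comparison (closed interval: a band at exactly 300 or 5000 bp is kept,
since only bands strictly beyond the window are unreliable).

Similarity between two profiles is the *whole-curve Pearson correlation*:
each profile is rasterized onto a 1000-point grid uniform in log~10~(bp)
(gel migration is approximately linear in log fragment size) as a sum of
Gaussian peaks, and the correlation is maximized over small global shifts.
Two parameters, both expressed as fractions of the grid span, control the
comparison:

* `tolerance` (default 0.005, i.e. 0.5%) — the Gaussian kernel width; bands
  closer than this blur together, implementing band-matching tolerance.
* `optimization` (default 0.005) — the half-range of the global shift
  search, absorbing small residual calibration offsets. The shift applies
  to the whole curve; per-band shifting is not attempted.

The similarity matrix feeds three consumers: UPGMA clustering
(size-weighted average linkage on `d = 1 - s`, lexicographically smallest
label pair on ties so the merge sequence is deterministic), strain
deduplication (single-linkage components at similarity >= 0.90, one
representative per component, lowest id — the criterion treats strains
within 90% similarity as the same genotype), and the covariance of the
relatedness-adjusted regression described below. `d = 1 - s` is the
simplest monotone transform; merge heights are only compared internally, so
the choice is inconsequential downstream.

## From raw assay readings to eight properties

`build_property_table()` produces one row per strain with eight properties.

* **Hydrophobicity** — MATH assay: `(initial OD546 - aqueous OD546) /
  initial OD546`; readings where the aqueous phase exceeds the initial OD
  (measurement noise) clamp to 0 with a warning.
* **Zeta potential** — a pass-through instrument measurement; the package
  deliberately does no electrokinetic theory.
* **Net charge vs pH** — from a sample and a cell-free blank titration
  (pH 4 to 10), the charge per 10^8^ cells is the acid–base balance
  difference
  `[(C_A - C_B - [H+] + [OH-])_sample - (C_A - C_B - [H+] + [OH-])_blank] / N_bact * 1e-3`
  with concentrations in mmol/L and pK~w~ = 14. Both terms carry `+[OH-]`:
  the printed source formula has opposite hydroxide signs in the two terms,
  which would give a nonzero "charge" for a sample identical to the blank,
  contradicting its own definition as a sample-minus-blank difference; the
  asymmetric variant remains available via `literal_sign = TRUE`. Titration
  records are interpolated piecewise-linearly in pH onto a common grid
  (titrator records are dense and monotone), replicate profiles are
  averaged after charge computation, and no extrapolation outside the
  titrated range is permitted.
* **Net charge at pH 8.0** — linear interpolation at the common stream pH.
* **Total acidity** — net charge at pH 4.0 minus net charge at pH 10.0.
* **Point of zero charge (PZC)** — the first sign change of the profile
  scanning upward from pH 4, by linear interpolation between bracketing
  grid points; later crossings are kept in an attribute, and a profile that
  never crosses zero has `NA` PZC (absent, not zero).
* **EPS protein and sugar** — absorbances inverted through ordinary
  least-squares standard curves (BSA for the Lowry protein assay, xanthan
  gum for the phenol–sulfuric sugar assay), normalized to µg per 10^8^
  cells by the assayed cell count.
* **Protein/sugar ratio** — elementwise; note this column is structurally
  correlated with both parents, which the correlation analysis must flag,
  not hide.

## The inferential layer

**Two-group comparison.** Each property is compared between habitats with
the Wilcoxon rank-sum (Mann–Whitney) test, midranks for ties, exact
enumeration for small tie-free samples and the tie-corrected normal
approximation with continuity correction otherwise. A paired signed-rank
variant is sometimes named for this kind of comparison, but it cannot
apply to independent groups of unequal size (here 44 vs 33); the rank-sum
form is the test the design admits.

**Correlation structure.** All property pairs get Kendall tau-b (tie
corrected) with two-sided p-values, computed for all strains and within
each habitat, dropping incomplete pairs pairwise. No multiplicity
correction is applied to match the per-property reporting convention; a
Benjamini–Hochberg column is emitted alongside for the reader.

**Mantel test.** The association between genomic similarity and habitat is
tested by correlating the strain-pair similarities with a habitat
*co-membership* indicator (1 = same habitat), so a positive statistic
literally reads "similarity is larger within habitat". Distance coding
(0 = same) is available and flips the sign. Significance comes from joint
row/column permutations with the `(1 + #{r* >= r}) / (1 + n_perm)` rule,
one-sided greater by default (the hypothesis has a direction), 9999
permutations by default. Strains are internally put in canonical label
order first, so the permutation p does not depend on incidental row order.
Note the attainable minimum p is slightly above `1/(1 + n_perm)`: any
permutation that maps the habitat partition onto itself reproduces the
observed statistic exactly and counts as a tie.

**Relatedness-adjusted regression.** For each property,
`pgls_fit()` estimates `y = b0 + b1*1{sediment} + e` with
`Var(e) = sigma^2 V`, where `V` is the repaired similarity matrix — the
generalized-least-squares analogue of phylogenetic regression with the
fingerprint similarity playing the role of the phylogenetic correlation.
`V` is fixed; no mixing parameter (Pagel-lambda style) is estimated. The
fit is computed through the Cholesky factor of `V` (whitening, no explicit
inverse), with a two-sided t-test on n − 2 degrees of freedom for the
habitat coefficient.

### Conditioning of the similarity covariance

Shift-optimized curve correlation matrices are not positive semi-definite
(the elementwise maximum over shifts breaks PSD-ness), and their spectrum
decays essentially to zero. `similarity_to_covariance()` therefore
eigendecomposes, floors the eigenvalues, and reconstructs. The floor
matters: a GLS fit weights each eigen-contrast of `V` by `1/eigenvalue`,
so flooring near zero (e.g. 1e-8 of the top eigenvalue) lets contrasts
between near-identical fingerprints dominate the fit. Those contrasts are
exactly where the response carries assay measurement error rather than
genomic signal: in simulation, adding a realistic iid noise component
(residual sd 0.05 on a hydrophobicity effect of 0.2) collapses the 95% CI
coverage of the habitat effect to about 0.35 under a 1e-8 floor. The
default floor of 0.01 instead caps the condition number of the repaired
matrix at 100, bounding the weight ratio between the most- and
least-trusted contrasts; under it the same simulation covers at ~0.94 with
an unbiased effect estimate. A tiny floor remains available for pure PSD
repair when the matrix is not used for fitting. The eigenvalue before and
after repair is attached to the result so every fit records its
conditioning.

## The synthetic-cohort generator

Because no raw strain data are deposited, the generator is the test bed:
it emulates the statistical structure the analysis assumes, with every
latent value recorded.

* **Fingerprints.** A pool of candidate band positions (default 30,
  log-uniform in [350, 4700] bp) is split into a shared fraction
  (`shared_band_fraction`, default 0.8) available to both habitats and
  habitat-exclusive remainders. Each strain carries each band of its
  habitat pool with probability 0.6 and log-normal intensity (sdlog 0.4,
  chosen to put pairwise curve correlations in the 0.3–0.8 working range
  without modelling gel optics). Between-habitat pairs share only the
  shared positions, so within-habitat similarity exceeds between-habitat
  similarity, shrinking to zero contrast as the shared fraction reaches 1.
* **Traits.** `y = mu + beta*1{sediment} + g + eps` with
  `g ~ MVN(0, sd_g^2 V)`, `V` the realized (repaired) similarity of the
  cohort just generated, and iid `eps`. Defaults place the six directly
  simulated properties inside the ranges reported for environmental
  *E. coli* isolates (e.g. hydrophobicity baseline 0.30 with sediment
  effect +0.15 against a 0.01–0.90 field span; zeta potential −22 mV with
  no habitat effect)
  with per-property variance components; the distributional shape (normal
  on the property scale) is a modelling choice, not an empirical claim.
  Physical guards clamp realized traits into admissible ranges
  (hydrophobicity into (0, 1)); the guarded value is the recorded truth.
  The guards truncate tails, so calibration studies that need an exactly
  correct model use the unguarded zeta potential.
* **Titrations.** Each strain's charge profile is
  `offset - sum(d_i / (1 + 10^(pKa_i - pH)))` — a multi-site
  Henderson–Hasselbalch model (default sites near pKa 4.8, 6.9, 9.4 for
  carboxyl, phosphate and amine/hydroxyl chemistry) with a positive offset
  so a PZC exists. The per-strain site scale and offset are solved from
  that strain's true total acidity and net charge at pH 8, and cumulative
  base additions are chosen so the assay-side balance recovers the model
  exactly; curves are noise-free by default (a `titration_noise_sd` knob
  exists), keeping round-trip recovery exact.
* **MATH, EPS, markers.** Optical densities and absorbances are
  back-computed from the true traits through the known formulas and
  standard curves; quadruplex marker profiles are drawn from per-habitat
  phylotype frequency tables and mapped to genotypes that the lookup
  assigns back to the same label.
* **Reproducibility.** All randomness flows from one integer seed, split
  into per-stage substreams by an avalanche hash (linearly related
  Mersenne-Twister seeds can carry initialization correlations); the same
  configuration reproduces a bit-identical cohort.

What the generator does *not* emulate: gel optics and lane distortion,
assay-specific error shapes (all noise is Gaussian), dependence between
properties beyond the shared genomic effect, and real phylogenetic tree
structure (relatedness enters only through the realized similarity
matrix). Passing tests therefore demonstrate the statistical machinery is
correct and calibrated under the assumed structure, not that real
fingerprints satisfy that structure.

## Numerical choices and degenerate inputs

* Quartiles use R's default type-7 rule; the boxplot five numbers are
  (Q25 − 1.5·IQR, Q25, median, Q75, Q75 + 1.5·IQR) with points beyond the
  whiskers reported as outliers.
* Exact enumeration limits: rank-sum exact when n1 + n2 <= 12 and
  tie-free; Kendall exact when n <= 8 and tie-free; both otherwise use
  their standard approximations.
* A strain with no bands left after size filtering is excluded from
  similarity with a logged warning; a strain whose profile never crosses
  zero has absent PZC; a constant property yields p = 1 in the comparison
  and NA correlation entries; per-property failures in the report warn and
  leave a NULL slot without aborting other properties.
* The pipeline (`run_all()`) records per-stage status, output hashes,
  timings and dropped strains in `manifest.json`; a stage failure skips
  downstream stages.

## Problem sizes used in tests and calibration

The packaged calibration studies use 20 + 20 strain cohorts: 500 null
cohorts (fully shared band pool, zero effects, zero residual noise — the
trait covariance is then exactly `sd_g^2 V`, the condition under which the
GLS t-test is exact) for type-I error of the Mantel and GLS habitat tests,
and 500 cohorts with a true hydrophobicity effect of 0.2 (sd_g 0.1,
residual sd 0.05) for bias and CI coverage. The bias check subtracts each
cohort's realized latent habitat contrast (recorded in the truth bundle) as
a control variate, since the raw Monte-Carlo mean of the estimate carries
the cohort-level noise contrast on top of any estimator bias. Oracle checks run UPGMA against
an exhaustive agglomerator on 200 random matrices (n <= 7), Kendall tau
against brute-force pair counting (n <= 50), and the exact rank-sum p
against full enumeration for all splits with n1 + n2 <= 10. The
study-scale demonstration cohort is 44 + 33 strains, matching the design
the workflow targets.

## Worked example

```{r example, eval = FALSE}
library(colisurf)

cfg <- cohort_config(n_sediment = 12, n_water = 12, seed = 1)
cohort <- generate_cohort(cfg)
tab <- build_property_table(cohort)

report <- habitat_report(tab, cohort$similarity, n_perm = 999, seed = 1)
report$mantel
report$properties$hydrophobicity$wilcoxon
report$properties$hydrophobicity$pgls
```

The repository's `analysis/` scripts run the same chain at study scale
(44 + 33) stage by stage, writing their tables under `results/`; see the
README for the numbers a run prints.

## Known limitations

* The fixed-`V` GLS has no mixing parameter: if genomic relatedness
  explains little of a property's variance, the fit over-discounts and
  loses power relative to a lambda-estimating variant.
* The Mantel test's co-membership coding tests association with the
  habitat partition, not any particular between-group distance scale.
* PZC estimation assumes the charge profile crosses zero at most a few
  times in [4, 10]; heavily oscillating profiles (noisy titrations) report
  only the first crossing.
* Real fingerprint similarity matrices may be farther from PSD than the
  shift-max construction produces; the condition-number cap handles both,
  but extreme rank deficiency (many near-identical strains) should be
  resolved by deduplication before regression, as the workflow does.
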