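Package: colisurf
Title: Habitat Analysis of E. coli Cell-Surface Properties with
    Fingerprint-Based Relatedness
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Workflow for comparing cell-surface properties of E. coli
    strains isolated from stream sediments and the overlying water column.
    Computes pairwise genomic similarity from (GTG)5 rep-PCR densitometric
    fingerprints (whole-curve Pearson correlation with band-matching
    tolerance and shift optimization), clusters strains by UPGMA,
    deduplicates at a 90 percent similarity criterion and assigns Clermont
    phylotypes. Converts raw assay readings (MATH optical densities,
    potentiometric titrations, Lowry and phenol-sulfuric absorbances) into
    eight surface properties. Provides the inferential layer: rank-sum
    habitat comparisons, Kendall tau-b correlation structure, a Mantel
    permutation test of similarity against habitat co-membership, and
    generalized least squares with the similarity matrix as residual
    covariance to estimate habitat effects net of genomic relatedness.
    Includes a synthetic-cohort generator with known ground truth for
    calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
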