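Package: abdev
Title: In Silico Antibody Developability Screening from Structure and Sequence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Structure- and sequence-based developability profiling of antibody
    Fab/Fv candidates. Computes solvent-accessible surface area (SASA) with a
    from-scratch Shrake-Rupley implementation validated against analytic and
    Monte Carlo oracles, converts per-residue SASA into hydrophobicity scores
    via the Black-Mould scale, classifies hydrophobic hotspots on Kabat-annotated
    CDR/framework regions, scans sequences for post-translational-modification
    liability motifs (deamidation, N-glycosylation, Asp isomerization, DP
    proteolysis) and solvent-exposed oxidation-prone residues, analyses
    inter-Fab hydrophobic interfaces and buried surface area, compares
    structures by Kabsch superposition RMSD and normalized B-factors, and
    implements the companion assay analytics: four-parameter logistic
    dose-response fitting with log-ratio relative potency, AC-SINS quadratic
    plasmon-peak extraction, and size-exclusion chromatography molecular-weight
    calibration. A synthetic-fixture generator with analytic ground truth makes
    the whole pipeline testable without downloading any structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
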