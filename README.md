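# abdev — in silico antibody developability screening

Therapeutic antibodies can fail in the clinic for reasons unrelated to
affinity: exposed hydrophobic patches drive self-interaction, aggregation,
fast clearance and short half-life. `abdev` implements the
structure- and sequence-based screen used to diagnose and engineer away such
liabilities in an antibody Fab/Fv, and the analytics for the companion
biophysical assays. It is aimed at antibody engineers and structural
bioinformaticians who want a reproducible, scriptable version of this screen
with every numerical choice pinned and testable offline.

## What it computes

**Surface hydrophobicity.** Per-residue solvent-accessible surface area
(SASA) by a from-scratch Shrake–Rupley implementation (probe radius 1.4 Å,
960 golden-spiral quadrature points by default, Bondi-type radii), then the
per-residue hydrophobicity score

```
score_r = SASA_r × h_aa
```

where `h_aa` is the Black–Mould normalized hydrophobicity index
(Phe = 1.000, Arg = 0.000). Scores aggregate exactly over Kabat regions
(CDR1–3, FR1–4) and chains, and classify into *elevated* (≥ 100) and
*moderate* (≥ 50) hydrophobic hotspots. The engine is validated against two
independent oracles: closed-form sphere/spherical-cap areas and a Monte
Carlo rejection estimator.

**Sequence liabilities.** Motif scan for Asn deamidation (SNG/ENN/LNG/LNN),
N-glycosylation sequons (N-X-[S/T], X ≠ P), Asp isomerization
(DS/DN/DQ/DK/DL) and DP proteolysis; structurally exposed oxidation-prone
Met/Trp (relative SASA ≥ 0.2 of Gly-X-Gly maxima); rare framework residues
against a germline position-frequency table (< 2% by default, CDRs never
flagged).

**Interfaces and comparisons.** Inter-Fab heavy-atom contact detection
(4.5 Å cutoff), per-residue buried SASA across an interface, hydrophobic
interface character; Kabsch rigid-body superposition RMSD; normalized
B-factors `z = (B − μ)/σ` (population convention).

**Assay analytics.** Four-parameter logistic dose–response fits
(`response = bottom + (top − bottom)/(1 + (EC50/conc)^hill)`) with the
log-ratio relative potency `potency% = log10(EC50_ref)/log10(EC50_sample) ×
100`; AC-SINS plasmon-peak extraction by quadratic fit over 500–560 nm with
`λmax = −b/2a` and Δλmax vs a control; SEC molecular-weight estimation from
a `log10(MW)` vs retention-volume calibration line.

**Synthetic fixtures.** `make_toy_structure()`, `make_liability_sequence()`
and `make_assay_fixtures()` generate seed-deterministic PDB/FASTA/CSV
fixtures with analytic ground truth, so the entire pipeline is testable
without downloading anything.

## Worked example

```r
library(abdev)

st   <- read_structure("mini.pdb")                       # PDB or mmCIF
st   <- apply_numbering(st, read_numbering_map("numbering.csv"))
sasa <- compute_sasa(st)                                 # Shrake-Rupley
prof <- score_profile(sasa)                              # SASA x Black-Mould
prof$residues[, c("scheme_label", "aa", "region", "sasa", "score")]
#>   scheme_label aa region  sasa  score
#> 1          H97  W   CDR3 120.8 106.03
#> 2          H31  I   CDR1 120.8 113.88
#> 3          H40  S    FR2 120.8  43.35
#> 4          L93  W   CDR3 120.8 106.03
#> 5          L30  M   CDR1 120.8  89.12
#> 6          L50  G   CDR2 120.8  60.50

classify_hotspots(prof)
#> <hotspot_report> elevated (>= 100): H97, H31, L93
#>                  moderate (>= 50): L30, L50

flag_exposed_oxidation_sites(st, sasa)[, c("scheme_label", "aa", "rel_exposure")]
#>   scheme_label aa rel_exposure
#> 1          H97  W        0.424
#> 2          L93  W        0.424
#> 3          L30  M        0.539

relative_potency(148, 518)     # reference vs weaker-binding sample, pM
#> [1] 79.95571
```

Here every residue is a fully exposed single-atom sphere (SASA
4π(1.7 + 1.4)² = 120.8 Å²), so the scores are the Black–Mould indices scaled
by one constant: the two CDR3 tryptophans and the CDR1 isoleucine classify
as elevated hotspots, and the exposed Met/Trp are flagged as oxidation-prone.
On a real Fab the same calls profile the full structure; `run_screen()`
orchestrates all stages from a single config and writes a JSON report.

The deposited crystal structures this screen was designed around (PDB 6FOE,
the parent Fab; PDB 9FQO, the engineered variant) are not shipped: fetch
them once with `Rscript scripts/fetch_structures.R` (network required) and
the structure-integration tests will exercise them.

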