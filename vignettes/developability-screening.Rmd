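---
title: "Methods: structure- and sequence-based antibody developability screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structure- and sequence-based antibody developability screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abdev)
```

## The problem and the model

Exposed hydrophobic surface on an antibody's variable domains correlates
with self-interaction, aggregation, fast clearance and immunogenicity.
`abdev` quantifies this risk from a crystal structure or model with a
single, deliberately simple score: for every residue

$$\mathrm{score}_r = \mathrm{SASA}_r \times h_{aa(r)},$$

the product of the residue's solvent-accessible surface area (Å²) and its
Black–Mould normalized hydrophobicity index (dimensionless, Phe = 1,
Arg = 0). A buried tryptophan contributes nothing; a fully exposed one
contributes strongly. The score is linear in SASA by construction, so
region scores and chain totals are exact sums of their members, and any
rescaling of SASA propagates proportionally — both properties are enforced
by tests.

The screen around this score covers four evidence streams a developability
assessment combines: (1) hydrophobic hotspots and their clustering at
inter-Fab crystal contacts, (2) sequence liability motifs, (3) exposed
oxidation-prone residues and rare framework positions, and (4) the
biophysical assay readouts (binding potency, self-interaction, size
homogeneity) used to validate engineered variants.

## SASA: algorithm and numerical choices

SASA is computed with the Shrake–Rupley rejection method, written here from
first principles because it is the quantity everything else depends on.
Each atom's van der Waals sphere is inflated by the probe radius; a
deterministic golden-spiral (Fibonacci) point set is placed on the inflated
sphere; points inside any neighboring inflated sphere are buried; the
accessible area is the exposed fraction times the sphere area.

Choices that affect the numbers, with defaults and rationale:

* **Probe radius 1.4 Å** — the conventional water probe.
* **960 quadrature points** — isolated-sphere error is below 1% and the
  per-atom cost stays trivial; the point count is a parameter and accuracy
  increases monotonically with it.
* **Radius table** — a pinned Bondi-type element table (`vdw_radii()`).
  Published SASA implementations differ in radii and quadrature at the
  several-percent level; comparisons against values computed elsewhere
  should allow ~10% relative slack for this reason.
* **Hydrogens dropped, waters (HOH/WAT) and heteroatoms excluded** by
  default — crystal structures are heavy-atom dominated and solvent should
  not occlude protein surface. All are flags.
* **Altlocs** — highest occupancy wins; ties keep the alphabetically first
  conformer. Stated because depositions are inconsistent here.
* **Neighbor search** — a uniform spatial grid with cell size
  2·(r_max + probe). Correctness, not speed, is the contract: the grid is
  tested for exact equality against an all-pairs search on dense and
  sparse packings.

Two independent oracles validate the engine. Closed forms: an isolated
sphere has area $4\pi(r+p)^2$ and each of two equal intersecting spheres
loses a cap $2\pi R h$, $h = R - d/2$. A Monte Carlo estimator (uniform
points on each inflated sphere, rejection against all other spheres) gives
an unbiased area estimate with binomial standard errors. One statistical
subtlety: the suite compares ~170 atoms simultaneously, so a "within 3 SE
per atom" criterion would falsely fail about a third of runs; the tests
therefore apply a Šidák family-wise correction (nominal 1% error) plus a
requirement that ≥ 98% of atoms sit inside the plain 3 SE band.

## Numbering, regions and hotspots

The package does not renumber sequences. It consumes a user-supplied
numbering map (CSV: chain, resnum, icode, aa, scheme_label, region) and
ships the Kabat CDR boundary table (H1 31–35, H2 50–65, H3 95–102, L1
24–34, L2 50–56, L3 89–97; insertion letters inherit their parent number's
region). Scheme assignment from sequence is an external-tool concern;
pinning the map removes ambiguity and makes region aggregation exactly
reproducible. An empty map degrades to region `other` without error.

Hotspot thresholds are score units: **elevated ≥ 100**, **moderate ≥ 50**.
The choice is anchored by the fully exposed CDR3 tryptophan case: a Trp at
157 Å² scores 157 × 0.878 ≈ 137.8, firmly elevated, while mid-exposure
hydrophobics land in the moderate band. Both thresholds are plain
parameters and are echoed in every report.

For structures with two Fab copies in the asymmetric unit, per-residue
values can be reported per copy or averaged; single-copy mode is used for
structure-to-structure deltas, where residues pair by scheme label and
deltas are reported as `b − a` with unpaired labels listed separately.

## Sequence liabilities

The motif rule set is deliberately literal: deamidation trimers SNG, ENN,
LNG, LNN; the N-glycosylation sequon as a positional rule (N at i, not-P at
i+1, S/T at i+2) rather than a string; DP proteolysis; and DS/DN/DQ/DK/DL
isomerization. All occurrences are reported, including overlaps, ordered by
position. Generic NG/NS dipeptides are *not* scanned by default — the rule
set is exactly the four trimers, extensible via `motif_rules()`. The
scanner is property-tested against a brute-force all-window matcher on
random sequences.

Oxidation risk is structural, not sequence-contextual: every Met and Trp
whose relative exposure (residue SASA over the pinned Gly-X-Gly theoretical
maximum, Tien et al. 2013 values) reaches 0.2 is flagged. "Highly
solvent-exposed" has no canonical number; 0.2 is the default and is
surfaced in config and reports.

Rare framework residues are flagged when the observed amino acid's
frequency at that scheme position in a user-supplied germline repertoire
table falls below 2%; CDR positions are never flagged, and an amino acid
absent from a known position counts as frequency 0.

## Interfaces

Inter-group contacts use a 4.5 Å heavy-atom cutoff (exhaustive residue-pair
search, symmetric under group swap, monotone in the cutoff). Burial is
`SASA(residue | own group alone) − SASA(residue | complex)`, clamped at
zero against quadrature jitter; on the two-sphere fixture it equals the
analytic cap area 34.21 Å². A residue counts as hydrophobic at the
interface when its Black–Mould index reaches 0.7, which admits exactly
{F, W, Y, L, I, V, M}; interface residues are ranked by buried area × h.

## Structure comparison

Superposition uses the Kabsch SVD solution with the determinant correction,
so reflections can never masquerade as rotations; RMSD is validated against
a numeric optimizer over rigid motions. Default pairing is CA atoms matched
by scheme label (insertion codes ride along in the label); backbone and
all-atom policies exist. B-factors normalize as $z = (B-\mu)/\sigma$ with
the **population** σ (the formula's "standard deviation" is ambiguous;
population gives exactly zero mean and unit variance, and the sample
convention is a switch). Normalization pools whatever values are passed —
pooling the asymmetric unit vs per-chain is the caller's slicing decision.

## Assay analytics

**4PL.** `response = bottom + (top−bottom)/(1+(EC50/conc)^hill)`, fitted by
Levenberg–Marquardt on `log10(EC50)` with deterministic initialization:
asymptotes from the response extremes, EC50 by mid-response log
interpolation, hill ±1 by the sign of the response-vs-log-concentration
slope. The canonical result keeps bottom < top with the curve direction in
the hill sign. Flat data and solver failure return `converged = FALSE`,
never a silent answer.

**Relative potency** is `log10(EC50_ref)/log10(EC50_sample) × 100`. The
formula is unit-dependent — logs of values ≤ 1 flip sign — so inputs are
pM by convention and values ≤ 1 pM are refused rather than misinterpreted.
Log base 10 is assumed; the ratio is base-invariant anyway.

**AC-SINS.** Ordinary least-squares quadratic over the 500–560 nm window
(endpoints inclusive, actual wavelengths used, irregular grids tolerated);
the peak is the vertex −b/2a, flagged invalid when a ≥ 0 or the vertex
leaves the window. The reported quantity is the shift against an explicit
control spectrum.

**SEC.** Linear `log10(MW)` vs retention volume over the standards; the
slope must be negative; queries outside the standard range by more than a
guard band warn about extrapolation. With two standards the line
interpolates them exactly.

## Synthetic fixtures: what they emulate, and what they do not

The generators produce: toy structures with analytically known SASA
(single sphere, two-sphere, a 12-atom icosahedral cage whose enclosure of
the central atom is verified numerically, random clusters); liability
sequences whose background alphabet {A,G,V,F,H,R,K,P} provably cannot form
any default motif, so planted hits are the only hits; AC-SINS spectra on
the 480–580 nm, 2 nm grid with additive Gaussian noise; 4PL curves at
log-spaced concentrations with multiplicative log-normal noise; Gaussian
B-factor sets; and SEC standards on a known line. Every generator is
seed-deterministic to the byte and writes a truth JSON describing exactly
what it planted.

Default generator conditions mirror the assay designs they emulate: 12
concentrations for binding curves, EC50 200 pM and a Hill slope of 1 in the
mid-range of reported Fab affinities, 2% multiplicative response noise for
the noisy-recovery checks; AC-SINS curvature −0.001 AU/nm² with 0.005 AU
additive noise, vertex at 530 nm (the plasmon peak of 20 nm gold
conjugates); SEC standards spanning 1.35–670 kDa.

What passing these tests shows: the geometry, scanning and fitting
machinery is correct against independent oracles. What it does not show:
agreement with any particular published SASA implementation beyond ~10%
(radius/quadrature conventions differ), behavior on NMR ensembles or
models with hydrogens, or motif relevance outside the encoded rule set.
Real crystal structures additionally stress altloc/insertion-code handling,
which is covered by construction in the parser tests but at toy scale.

Problem sizes used by the default suite — 20 random 3–15-atom packings for
oracle equivalence, 2000 Monte Carlo samples per atom, 300–1000 random
sequences for the scanner property, 20 noisy binding curves and 100 noisy
spectra — were chosen so the whole suite exercises every contract in under
a minute of compute while keeping every statistical bound comfortably
powered.

## The screen orchestrator

`run_screen()` runs parse → SASA → profile → hotspots → liabilities →
interface → comparison → assays in that fixed order, because each stage
consumes the previous stage's artifacts. A config without a structure
degrades to a sequence-only screen and says so; a config error aborts
before any computation. Reports echo every parameter verbatim, hash inputs
(md5) and are deterministic apart from the timestamp. The
`immunogenicity` slot is pass-through only: MHC-II epitope prediction is an
external-service concern and externally produced epitope lists can be
attached but are never computed here.

## Known limitations

* SASA is accessible-surface only; no solvent-excluded (Connolly) surface,
  no decomposition of an atom's burial by neighboring residue.
* No Kabat renumbering from sequence, no structure prediction, no MD — the
  screen consumes structures and numbering maps produced elsewhere.
* Crystallographic symmetry mates are not expanded; only chains present in
  the file participate in interface analysis.
* HIC retention is not modeled; hydrophobic-interaction chromatography
  enters only as the wet-lab validation it is.
* The deposited reference structures are not shipped; a fetch script
  exists, and the structure-integration tests state clearly when the files
  are absent.
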