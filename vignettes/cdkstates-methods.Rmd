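---
title: "Methods: comparing cyclin-free and cyclin-bound CDK1/CDK2"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing cyclin-free and cyclin-bound CDK1/CDK2}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdkstates)
```

## Scope and models

`cdkstates` quantifies why ATP-competitive inhibitors bind cyclin-free
CDK1 weakly while binding cyclin-free CDK2 and the cyclin-bound
complexes tightly, using two families of measurements: structural
metrics on kinase coordinates and binding thermodynamics on titration
data. This vignette records the models, the defaults and their
rationale, the numerical choices, and what the synthetic-data tests do
and do not establish.

## Structure handling

Coordinates are read from PDB or mmCIF (via bio3d) with author residue
numbering preserved and no coordinate transformation. Standard
filtering removes hydrogens and resolves alternate locations by keeping
the highest-occupancy altloc, ties broken lexicographically — the
deterministic convention most contact software uses. Waters and all
HETATM records are excluded from every structural metric. When several
kinase copies sit in the asymmetric unit the first kinase chain by
chain-id sort order is analyzed; copies are never averaged, because
averaging mixes distinct lattice environments.

The *element map* partitions the kinase chain. CDK defaults: P loop
11–17, hinge 81–84 (anchored on the E81/L83 inhibitor hydrogen-bonding
residues), N-lobe = chain start through residue 80 (the residue
preceding the hinge), C-lobe = residue 85 to the chain end, C helix
46–57, activation segment 146–173 (CDK1, DFG→APE) or 145–172 (CDK2),
gatekeeper F80, P-loop tyrosine Y15, activation-segment glutamate E163
(CDK1) / E162 (CDK2). The β-sheet-base span, the C-helix limits and the
R-/C-spine residue lists are *configuration defaults*: no deposited
annotation fixes them uniquely, so they live in
`inst/extdata/cdk_elements.tsv` and can be overridden per kinase and
element from a YAML/JSON config (`element_map_from_config()`), each
value an inclusive `[start, end]` pair or a residue list. The spine
lists follow the conserved protein-kinase spine assignment — the
C-helix leucine (L55) and the DFG phenylalanine sit on the R-spine —
with the HRD histidine and β4 leucine completing it.

## Contact census

The census counts unordered heavy-atom pairs (a, b), a in an N-lobe
residue and b in a C-lobe residue of the kinase chain, at distance
strictly below the cutoff (default 4.0 Å; the strict `<` is the
boundary convention of the comparison this package implements).
Candidate pairs come from a cell-list grid with cell edge equal to the
cutoff and a 27-cell neighborhood — an exact decomposition, so the grid
result equals the all-pairs double loop, and the test suite asserts
that equality on 100 random fixtures. Counts are monotone
non-decreasing in the cutoff by construction. In `element_pairs` mode
each contact is attributed to named elements (P loop, C helix, β-sheet
base on the N side; activation segment, hinge on the C side; remainder
otherwise); an element with no atoms yields a warning, not an error,
because partial models are common.

`compare_states()` ranks labelled censuses by total count, flags the
minimum (all tied rows on a tie), and refuses mixed cutoffs.

## Superposition

Residue pairing uses global sequence alignment (Biostrings; match +1,
mismatch 0, gap −1) of the chains' one-letter sequences, so chains with
shifted author numbering pair correctly; only residues with a Cα
participate. The rigid transform is the Kabsch solution: SVD of the
cross-covariance of centered coordinate sets, with the determinant sign
correction that rejects reflections; degenerate (collinear) sets raise
a distinct error. The default atom set is Cα over all paired residues —
the "global superposition" convention — because side-chain disorder
makes all-atom RMSDs sensitive to modelling choices; `all_heavy` is
available and matches atoms by name within paired residues. Tests pin
the implementation to a one-dimensional rotational grid search on
planar toys (agreement within 1e-4 Å) and to an independent
least-squares fit, and assert exact recovery (RMSD < 1e-8 Å) under
planted proper rigid motions.

## Spines and the P loop

Spine assembly is scored per link: the minimum distance between
side-chain heavy atoms (backbone N, CA, C, O, OXT excluded) of
consecutive spine residues, broken iff the gap exceeds `link_threshold`
(default 4.5 Å — an upper bound for van-der-Waals stacking of aliphatic
side chains with modest tolerance; glycines or missing side chains
break their links). The assembled flag is monotone in the threshold.

The P-loop tyrosine classifier measures two distances from the tyrosine
hydroxyl: `d_glu` to the nearer activation-segment glutamate
carboxylate oxygen, and `d_pocket` to a ligand-independent pocket
reference (centroid of the gatekeeper side chain and the hinge Cα
atoms — computable for apo structures, which is why no ligand atom is
used). Labels: `popped_out` iff `d_glu <` the coordination threshold
(default 3.5 Å, the long edge of a hydrogen bond) and `d_glu <
d_pocket`; `tucked_in` iff `d_pocket` is within the pocket radius
(default 6 Å) and closer than the glutamate; otherwise
`indeterminate`, including whenever required atoms are missing. The
class is rigid-motion invariant because only internal distances enter.

## One-set-of-sites ITC

The forward model follows the perfusion-cell bookkeeping of standard
instrument software: an injection of volume dV expels the fraction
dV/V₀ of the cell contents *at pre-mixing composition*, then adds
titrant; the bound complex solves the single-site quadratic at the
post-injection totals; the differential heat is ΔH × (change in moles
of complex in the cell, correcting for expelled complex) + baseline.
The default schedule is the study protocol: 200 µL cell at 10 µM,
100 µM titrant, one 0.5 µL priming injection then 19 × 2 µL, 303.15 K.
Tests check the equilibrium against a bisection solver (1e-10),
mass-action/mass-balance identities (1e-12), and the stoichiometric
limit (Kd → 0: cumulative heat linear in injected titrant with a break
at molar ratio n).

The fit is Levenberg–Marquardt over (log Kd, ΔH, n, baseline); Kd on
the log scale keeps it positive, and the reported Kd standard error is
delta-method transformed. The priming injection is excluded from the
residuals (universal practice: its heat is corrupted by diffusion
during equilibration). Both floating and fixed n are supported, and the
baseline can be frozen, since published fits do not state either
choice. Initialization: n = 1, ΔH from the largest heat's sign,
Kd from the titrant concentration at half the cumulative heat. When the
c-value n·[cell]/Kd falls below 1 or the fitted Kd exceeds half the
maximal titrant concentration probed, the isotherm carries no Kd
information; the fit warns and records a lower bound, which affinity
tables render as `"> limit"` and exclude from fold arithmetic.

Signatures use ΔG = R·T·ln(Kd) with R = 1.9872e-3 kcal/(mol·K) and
T = 303.15 K by default; −TΔS = ΔG − ΔH, so ΔG = ΔH + (−TΔS) holds
identically, and ΔG(1 M) = 0 is exact.

## DSF, SPR, IC50

- DSF: Boltzmann sigmoid fit on the sweep up to the fluorescence
  maximum (the post-peak quench of dye-based melts is not part of the
  two-state transition, so it is excluded by default; an explicit
  window overrides). Temperatures must be strictly increasing; flat
  curves return `converged = FALSE`. ΔTm is a signed subtraction.
- SPR: hyperbolic steady-state fit, requiring ≥ 5 concentrations
  including the zero blank (the dilution-series design); a fitted Kd
  beyond the top concentration triggers a lower-bound warning.
- IC50: the logistic `Y = 1/(1+10^((logIC50 − x)·N))` with x = log10
  concentration. The printed form of this equation uses the
  concentration symbol directly, which is dimensionally inconsistent;
  reading the dose term as log10 concentration is the conventional
  interpretation and is recorded in the fit metadata. Zero doses cannot
  enter the log transform and are dropped with a count in the metadata.
  Y = 0.5 at the IC50 for any slope, which the tests assert on fitted
  parameters.

## Synthetic data: what it emulates, and what it does not

Generators are seeded (fixed seed ⇒ byte-identical output) and record
their ground truth as an attribute and as a `.truth.json` sidecar when
written to disk. Defaults mirror the experimental designs: the ITC
schedule above; 25–95 °C melts in 1 °C steps; the four-fold SPR
dilution ladder (0.05 → 12 500 nM, optionally 50 000 nM); the 12-point
0–6 µM activity titration. Noise is additive i.i.d. Gaussian. Study-
scale defaults used by the analysis scripts: 2% of the maximal heat for
ITC, 1 fluorescence unit (1% of the plateau) for DSF, 1 RU for SPR, 2%
activity for IC50 — values a well-behaved instrument run achieves.

Toy structures are alanine-like residues (5 heavy atoms) in two
separated blocks with exactly the planted number of inter-lobe pairs
under the cutoff and every other cross pair at least 0.5 Å beyond it,
by constructive spacing; planting is validated and infeasible requests
error. Rigid copies apply Euler-angle rotations (proper by
construction) plus translation and optional per-coordinate jitter; for
jitter σ applied to one copy, the fitted RMSD concentrates at √3·σ,
which the tests check over 50 seeds.

What passing these tests shows: the estimators invert their own forward
models at experimental noise levels, the census and superposition are
exact against brute-force oracles, and the pipeline's comparative logic
(ranking, fold tables, bounded-entry handling) is correct. What they do
not show: agreement with deposited crystal structures — real kinase
coordinates have correlated disorder, missing loops and lattice
contacts that no planted toy reproduces, and the element-range
calibration that fixes printed contact counts can only be performed
against deposited coordinates. The four per-state contact totals used
throughout (104, 133, 141, 145) are planted truths for machinery
validation, not derived quantities. Parameter values taken from
published affinity/stability tables (e.g. Kd 26 nM or 4400 nM, Tm
51.5 °C, ΔTm +8.9/−2.6 °C) are measurements: they enter only as
generator truths and table-formatting fixtures, never as computed
results.

## Problem sizes and determinism

Test and script workloads are sized for interactive turnaround:
random census fixtures of 10–500 atoms, 100 Monte-Carlo ITC replicates
and 50 IC50/jitter replicates, toy structures of ~100–300 residues.
All fitters are deterministic given identical data and initialization;
every stochastic check fixes its seeds. Reports rerun byte-identically
from the same config and seed.

## Known limitations

- No flexible or secondary-structure-aware alignment; pairing is
  global-sequence only, which suits near-identical kinase pairs.
- The ITC model is strictly one set of sites: no competitive,
  multi-site, or kinetic extensions; no dilution-heat blank subtraction
  beyond the constant baseline term.
- SPR fitting is steady-state only (no kon/koff), and no solvent or
  DMSO correction is modelled.
- The lobe boundary and element spans are conventions exposed as
  config; conclusions that depend on them should be checked under
  boundary perturbations (the acceptance tests perturb every boundary
  by ±1 residue and require the state ordering to survive).
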