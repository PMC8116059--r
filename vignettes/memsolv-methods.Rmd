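---
title: "Membrane structure maps and lipid-solvation thermodynamics: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane structure maps and lipid-solvation thermodynamics: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memsolv)
```

`memsolv` analyzes how the lipid solvent shapes a membrane-protein
dimerization equilibrium. This vignette records the models implemented, the
parameters that matter, what the synthetic-data generators do and do not
emulate, and the design decisions taken where more than one defensible
choice existed. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The scientific chain

A protein surface whose hydrophobic span is shorter than the bilayer's
creates a local defect: the membrane thins, lipids tilt away from the
bilayer normal, opposing leaflets interdigitate, and water penetrates the
acyl core. The cost of solvating that defect favors dimerization, which
buries the mismatched surface. A short-chain lipid species that solvates
the defect more comfortably becomes locally enriched there and stabilizes
the monomer — a preferential-solvation linkage, visible as a linear
dependence of the dimerization free energy on the logarithm of the
short-chain lipid activity. The package covers three measurement layers:
spatially resolved membrane-structure maps from bead configurations,
enrichment statistics for the two lipid species, and the single-molecule /
bulk-kinetics thermodynamics chain.

## Synthetic bilayers with planted ground truth

Microsecond-scale coarse-grained simulations are not reproducible at desk
scale, so every map operation is validated against *planted* ground truth:
a generator builds bilayer bead configurations whose local thickness, tilt
and species composition follow caller-supplied fields, and the test then
checks that the analysis recovers those fields.

Lipids are built from a fixed coarse-grained template: one headgroup bead
3 Å above the ester midpoint, two ester beads (GL1/GL2) 3 Å apart, and two
acyl tails of equally spaced chain beads (3 Å spacing; 5 beads per tail for
the long-chain PO species, 3 for the short-chain DL species, so the
nominal tail lengths are 15 Å and 9 Å and the chain end-to-end distances
12 Å and 6 Å). The granularity mirrors typical coarse-grained bead counts
without copying any force field. Placement is on a lateral lattice (~65 Å²
per lipid by default); ester planes sit at ±thickness(x, y)/2; tilt is
applied as a rotation about the ester midpoint with uniformly random
azimuth; species are independent Bernoulli draws from the local DL
fraction; a protein footprint (a disc) excludes lipids. Boxes are periodic
in x and y only.

Two sampling modes exist. A single frame places lipids exactly on the
lattice — useful for construction-exact tests (a noise-free flat bilayer
yields a thickness map that is exactly the planted constant). Multi-frame
generation (`n_frames > 1`) jitters each lattice site uniformly within its
cell, independently per frame, which emulates the dense spatial sampling a
time-averaged map enjoys in a long trajectory. This is a quenched ensemble,
not dynamics: `generate_trajectory()` separately provides lateral random
walks (with an optional region bias) for operations that need genuine
frame-to-frame correlation, such as the solvation-shell mixing metric.

What the generator does *not* emulate: excluded volume, elasticity,
curvature, realistic water structure, protein shape beyond a disc, or any
energetics. Passing planted-recovery tests therefore demonstrates the
correctness of the *analysis*, not the physics of real membranes.

## The grid engine

Per-lipid descriptor values are mapped onto square cells by adding the
value once to every cell whose center lies within the stamp radius of the
lateral position of either ester bead (the union of the two discs, no
double counting; the cell containing a bead is always stamped so a zero
radius degenerates to nearest-cell assignment). Occupancy counts accumulate
identically; the final map is the occupancy-weighted mean. Cells with
occupancy below 40 % of the mean occupancy — the mean taken over cells with
occupancy > 0, so that empty regions such as the protein footprint cannot
deflate it — are masked as not statistically significant.

Parameter choices: the cell edge defaults to 1 Å (configurable; the nominal
edge is adjusted per axis so an integer number of cells tiles the periodic
box), and the ester-bead van der Waals radius defaults to 2.6 Å, a typical
coarse-grained bead radius; neither value is sacred and both only set the
spatial smoothing scale of the maps. Distances to the protein are Euclidean
in the membrane plane, measured from the footprint boundary,
periodic-aware. Distance shells are sliding masks of fixed width (10 Å by
default) centered on the requested distances; a cumulative mode is also
provided.

## Descriptor conventions

* **Leaflets**: a lipid is `outer` when its headgroup sits above the
  frame's global ester midplane. A local-midplane variant was considered
  and rejected as unnecessary for the planar fixtures supported; strongly
  curved configurations are out of scope.
* **Tilt**: the lipid axis runs from the ester midpoint to the tail-end
  midpoint (headgroup excluded), and the angle is measured against the
  downward normal, so a vertical outer-leaflet lipid scores 0° and a
  vertical inner-leaflet lipid 180°. The bead-level definition of the axis
  is not uniquely determined by convention; the ester-to-tail-end choice
  tracks the acyl-chain tilt that drives hydrophobic thinning.
* **Interleaflet contacts** are counted as bead *pairs* within a cutoff
  (6 Å default, the first coordination shell at coarse-grained bead sizes)
  between a chain's beads and any opposing-leaflet chain bead; chain-pair
  counting was the alternative reading and is not implemented. Absolute
  values scale with the cutoff; planted fixtures make the tests
  cutoff-robust.
* **Water penetration** counts water beads between the *local* (per-cell)
  ester surfaces rather than global planes, because a thinning defect is
  precisely where global planes misclassify interior water.
* **Average conformations** accumulate bead positions laterally centered
  on each resident lipid's ester midpoint. Averaging a tilted lipid over a
  uniform azimuth contracts lateral offsets by (1 + cos θ)/2 and the axial
  extent by cos θ, collapsing both tails onto a vertical mean structure —
  the closed form the tests check against Monte-Carlo draws.

## Enrichment statistics

Per-cell percent enrichment compares the local DL/PO occupancy ratio with
the bulk ratio; distance profiles use sums of occupancies over shell
(optionally sector-restricted) masks rather than averages of per-cell
ratios — the two differ whenever the ratio varies within a mask, which a
two-cell counterexample in the tests makes explicit.

Two numerical properties matter in small boxes. First, the per-cell ratio
of small counts is biased upward (a Jensen effect), so per-cell maps are
only quantitative once cells have accumulated substantial occupancy; the
shell-aggregated profile is the robust statistic, and the tests assert
"positive only inside the planted bump" at that aggregated level, where
noise scales as the inverse square root of the occupancy sums. Second, the
default bulk ratio is the system's global species-count ratio (the preset
proportions); when a planted enrichment occupies a non-negligible area
fraction of a small box, the global ratio is itself inflated by the
enriched region, so `bulk_ratio()` accepts a far-field region as the
reference. In the acceptance analysis the enrichment extent is estimated
by fitting the raw shell DL/PO ratio to a Gaussian decay with a free bulk
level, which decouples the fitted width from the sampling noise of a
separately measured far-field ratio.

Interface sectors are angular sectors about the footprint center (default
three 120° sectors, the first centered on the dimerization axis). The
paper-level alternative — delineating interfaces by helix contacts — is
structure-specific; the axis-plus-angle parameterization generalizes it.

## The thermodynamics chain

The dimerization isotherm on the mole-fraction scale is
F = (1 + 4u − √(1 + 8u))/(4u) with u = K_eq χ\*. It is evaluated through
the algebraically identical conjugate form F = 4u/(1 + 4u + √(1 + 8u)),
which avoids the catastrophic cancellation of the textbook form at small u
(relative error there grows like ε/u²) and needs no series branch. The
tests confirm agreement with an independent numeric mass-action solver to
10⁻¹⁰ relative over twelve decades of u.

`fit_fraction_dimer()` implements exactly the least-squares linear
combination of fixed monomer and dimer control distributions, constrained
to [0, 1]. Its coefficient weighs the controls per visible *spot*. Because
a dimer carries two subunits but appears as one spot (visible with
probability 1 − (1 − p)², against p for a monomer), the spot coefficient g
and the fraction F of subunits in dimers differ; `subunit_fraction()`
applies the exact conversion F = g·b / (a(1 − g) + g·b) with
a = (1 − (1 − p)²)/2 and b = p. Recovery analyses therefore estimate g
against controls simulated under matched conditions (protein density,
labeling yield, liposome population — the computational analogue of
measuring the monomer and dimer control constructs in the same vesicle
preparation), convert to F, and only then invert the isotherm; matched
controls also cancel most of the co-capture distortion that heterogeneous
compartments introduce.

Free energies use ΔG° = −RT ln K_eq with R = 1.9872×10⁻³ kcal/(mole·K) and
a default temperature of 298.15 K (configurable; room-temperature work
could defend 295 K, which shifts ΔG° by about 1 %). ΔΔG is taken against
the mean reference free energy with quadrature error propagation. Isotherm
fits optimize log₁₀ K_eq with inverse-variance weights and report a
linearized standard error; fits where the dimer fraction never drops below
0.9, or where the implied K_D falls outside the sampled χ\* range by more
than a decade, are flagged as lower limits only, because the reaction is
out of the assay's dynamic range. Titration models (single and two-phase
exponential decay in %DL, F₀ fixable) constrain the fast-phase amplitude
F₁ to [0, 1]; published two-phase parameterizations in this assay family
have reported F₁ values far outside the unit interval, which is not
interpretable as a fraction under the model as written, so the constrained
form is used and model comparison relies on residual sums.

## The photobleaching simulator

One bulk monomer/dimer split is computed from the isotherm (equilibration
happens in large fused membranes before extrusion traps the distribution);
dimers and monomers are then assigned to liposomes by independent Poisson
draws with means proportional to compartment area (lognormal lipid-count
distribution, default median 2×10⁵ lipids with log-sd 0.8 and a 25 %
multilamellar fraction emulating a 400 nm extruded preparation; the
per-area proportionality constant is a free parameter, not calibrated to
any particular vesicle prep). Every subunit is labeled Bernoulli(p, default
0.663); a spot is a liposome with ≥ 1 fluorophore and its step count is the
total fluorophore count truncated into bins 1, 2 and 3+. Co-capture of
multiple species in one liposome is allowed and is what pushes the observed
distributions away from the pure binomial mixture at high occupancy; the
dilute-limit convergence to the analytic mixture is a tested property.
Fluorophore photophysics (blinking, bleach-time distributions) is out of
scope.

## Efflux kinetics

The two-exponential association model is fit by bounded
Levenberg–Marquardt with starts derived from the half-rise time. The model
is exchange-symmetric in its two components, so the faster fitted rate is
reported as the protein-mediated rate k_P; when either amplitude vanishes
(inactive-vesicle fraction near 0 or 1) the other component's rate is
unconstrained and the fit is flagged rather than silently reported. The
initial rate k_init is a linear regression over the first max(10 points,
5 % of the trace) — the window is configurable since no canonical width
exists — and converges to the analytic t = 0 slope
F₀,vol·k_leak + (1 − F₀,vol)·k_P as the window shrinks. Traces are assumed
normalized to the detergent-release total and to start at transport
initiation.

## Problem sizes and reproducibility

The test suite and acceptance analysis use bilayers of a few hundred
lipids per leaflet in ~125 Å boxes with tens to ~150 jittered snapshots,
simulated assays of 5 000–50 000 spots per condition, and 100-replicate
recovery studies — sizes chosen so the statistical bounds asserted (3σ
sampling bounds, median errors, CI coverage) are meaningful while a full
run stays within a few minutes on one CPU. Every stochastic step takes an
explicit seed; identical seeds give bit-identical outputs, and
`run_pipeline()` writes a manifest with parameters, seeds and output
hashes. Known limitations: two lipid species only, planar bilayers only
(no curvature or elastic moduli), disc footprints, and no support for
atomistic configurations.
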