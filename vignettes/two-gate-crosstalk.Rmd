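---
title: "Quantifying two-gate crosstalk in potassium-channel trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying two-gate crosstalk in potassium-channel trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinkgate)
```

## The model

The pore domain of MthK-like potassium channels is a tetramer whose
pore-lining inner helices carry a hinge glycine (Gly83) just below the
selectivity filter. Each inner helix switches between two conformations:

* **kinked** — the Val81–Gly85 and Leu82–Thr86 backbone hydrogen bonds are
  broken (Val81 O – Gly85 HN distance around 0.55 nm), the helix bends by
  roughly 43°, and the intracellular entrance of the selectivity filter is
  narrow;
* **bent** — the hydrogen bonds are formed (around 0.25 nm), the bend is
  roughly 30°, the filter entrance widens, but the Phe87 side chain rotates
  into the central cavity and dehydrates it.

This package treats the per-subunit state as a hidden two-state process and
measures its observable consequences: the Val81 O – Gly85 HN distance (the
state discriminator), the inner-helix bending angle, the Thr59 Oγ–Oγ ring
distance (filter-gate opening), the Ile84–Thr59 side-chain distance (the
mechanical link between kink and filter), the Phe87-CoF distance
(cavity-gate orientation), the Pro19 Cα–Cα distance (outer-helix spread),
K⁺ crossings of the filter (current), axial density / "free energy" and
pore-radius profiles, and membrane thickness from the lipid phosphate
layers.

The crosstalk picture this machinery quantifies: the channel conducts only
in *asymmetric* configurations. With all four subunits kinked the filter
gate is closed; with all four bent the filter gate is wide open but the
cavity is dehydrated; either symmetric extreme suppresses current.

"Free energy" is in quotation marks throughout: the profiles are Boltzmann
inversions of densities sampled under an applied voltage, i.e. a
nonequilibrium steady state, so only differences and shapes are meaningful,
not absolute thermodynamic values.

## State classification

Classification uses the Val81 O – Gly85 HN distance only; the bending
angle, the Leu82 O – Thr86 HN distance and the rest are corroborating
descriptors. A hysteresis rule labels a subunit bent below `t_low`
(default 0.27 nm, a standard donor–acceptor hydrogen-bond criterion) and
kinked above `t_high` (default 0.45 nm, safely outside bonding range);
inside the band the previous label is kept, which suppresses label flicker
while the distance sits near the barrier. The first frame takes the nearer
threshold, ties going to kinked (the more prevalent state). A
single-cutoff mode (band midpoint) is available for sensitivity checks.
For heavy-atom-only topologies the O–N distance can be substituted, in
which case both thresholds should be shifted by +0.1 nm (the N–H bond
length plus geometry).

The bent-state fraction `f_bent` is the mean of the bent indicator over
frames *and* subunits, so a tetramer with exactly one permanently bent
subunit has `f_bent = 0.25` by construction.

## Geometry conventions

* Units are nm and ns internally, degrees for angles, pA for currents,
  and kBT for energies; conversions happen only at I/O boundaries (DCD and
  PDB files store Å).
* The z axis is the membrane normal and pore axis; inputs with a different
  orientation must be rotated beforehand. Only orthorhombic boxes are
  supported; triclinic input is rejected explicitly.
* All pair distances use the minimum-image convention. Ion tracks are
  unwrapped along z before event detection.
* Cross-subunit ring distances (Thr59 Oγ–Oγ, Pro19 Cα–Cα, Ile84 COM ring)
  default to the mean of the two diagonal (opposite-subunit) distances;
  an all-pairs mode (mean of all six) is provided because the field's
  usage is not uniform.
* Side chains are non-backbone heavy atoms including Cβ; COMs are
  mass-weighted over heavy atoms, hydrogens excluded.
* The Ile84–Thr59 side-chain distance is intra-subunit by default (the
  two residues contact within a subunit in the fold).
* The bending angle is the angle between the first principal axes of the
  Cα sets on the two sides of the hinge (residues `[start, hinge-1]` and
  `[hinge+1, end]`), each axis oriented N→C; at least four Cα atoms are
  required per side, otherwise the subunit/frame is marked missing.
* Helix ranges are configurable with MthK defaults: inner helix 71–98,
  hinge 83, outer helix ending at Pro19, filter TVGYG at 59–63.

## Permeation counting

The filter slab is bounded by the Thr59 Oγ plane minus a margin and the
topmost filter carbonyl plane plus a margin (default 0.1 nm). A crossing
is counted by a three-compartment automaton (below / inside / above) only
when an ion's visited-compartment history completes below → inside →
above (+1, outward) or the reverse (−1): single-plane touches, bounces
and re-entries count nothing, which makes the count robust to long dwells
at the S4 site. This two-plane traversal rule is this package's
operationalization — trajectory papers typically state currents, not their
event detector. The automaton is property-tested against brute-force
compartment-sequence enumeration, exhaustively on all short sequences and
on random walks.

Currents are `I = (n⁺ − n⁻) e / t` with the CODATA elementary charge;
outward (intracellular → extracellular, +z) is positive, matching the
applied-field convention. The transmembrane voltage of a constant-field
setup is `V = E × L` with `L` the box height; 0.0325 V/nm in a 9.2308 nm
box gives 300 mV. Replicate aggregation reports mean ± SEM; a single
replicate reports SEM as missing, never 0.

## Profiles

Axial profiles count selected atoms in a cylinder (default radius 0.5 nm)
around the per-frame pore axis (xy centre of the filter Cα atoms), binned
at 0.05 nm — fine enough to resolve the ~0.3 nm spacing of the S1–S4
sites. z is measured relative to the Thr59 Oγ plane so profiles from
different replicates and systems superpose; the reference makes all
profiles invariant under rigid z-translation. The "free energy" is
−ln(density/max density), so the minimum is 0 by normalization (the true
zero is unknowable here) and barrier heights are computed as differences
only. Zero-density bins are masked, never reported as 0 or ∞.

The pore-radius profile takes, per z-slice, the minimum over nearby heavy
atoms of (xy distance to the axis − van der Waals radius), clamped to
[0, r_max]; empty slices report r_max and are flagged. By default slices
sit on the fixed per-frame axis — cheap and sufficient for gate trends —
with an optional per-slice grid search of the centre (0.02 nm step) for
HOLE-like output; full sphere propagation is deliberately not implemented.

Membrane thickness is the difference of the mean phosphate z per leaflet,
leaflets split by z about the phosphate COM per frame.

## Functional mode analysis

The collective motion maximally correlated with a scalar order parameter
(default: one designated subunit's bending angle) is extracted by
partial-least-squares regression (NIPALS PLS1) of the superposed, centred
backbone coordinates against the centred order parameter. The functional
mode is the normalized regression coefficient vector; extreme
conformations are the mean structure displaced along the mode to the 1st
and 99th percentiles of the observed projections. Superposition is a
Kabsch least-squares fit; the fitted atom set defaults to Cα/backbone
atoms because side chains are excluded from the collective-mode picture.

Frames are strongly time-correlated, so the train/validation split is a
contiguous 50/50 block and cross-validation uses contiguous folds —
random splits would be over-optimistic. Component count is chosen by the
one-standard-error rule over a blocked grid search, and a selection whose
best validation correlation falls below 0.5 is flagged unreliable. In the
full-rank limit PLS equals ordinary least squares, which the tests use as
an oracle; the mixOmics PLS implementation serves as an independent
cross-check of the fitted predictions. Note one practical caveat verified
in development: if the training block happens to contain a single
conformational state, the fitted mode is noise-dominated even though the
validation correlation can still look perfect — always check that both
states are visited in the training block (fast-switching synthetic data
uses gating rates of 0.8/ns for exactly this reason).

## The synthetic generator

The generator is a *statistical* emulator, not a physical model: helices
are parametrized Cα traces decorated with the named key atoms, and only
the quantities the pipeline measures are planted faithfully —

* per-subunit kinked/bent switching as four independent two-state Markov
  chains (exact discrete-time transition probabilities of the
  continuous-time chain; stationary bent fraction `k_kb/(k_kb+k_bk)`);
* kink templates: Val81 O – Gly85 HN distances 0.55/0.25 nm and bending
  angles 43°/30° for kinked/bent;
* the filter gate: Thr59 Oγ diagonal distance following the number of
  bent subunits through 0.497, 0.512, 0.519, 0.526, 0.533 nm for 0–4 bent
  (end points and the linear interpolation between them mirror the
  restrained-tetramer values the analysis should recover);
* the mechanical link: Ile84–Thr59 side-chain distances 0.54/0.59 nm;
* the cavity gate: Phe87-CoF distances 0.836 (kinked, out of the cavity)
  and 0.666 nm (bent, inside), which also produces the cavity constriction
  seen by the pore-radius profile, and a cavity water count that drops
  from 12 to 2 as the tetramer approaches all-bent;
* voltage-driven K⁺ crossings as Poisson events whose rate follows the
  configuration map `lambda_by_config = c(0, 54.7, 54.7, 25, 18)`
  events/µs for 0–4 bent subunits. The map encodes the crosstalk: zero
  conduction when all-kinked (closed filter), maximal for asymmetric
  configurations, suppressed again when all-bent (dehydrated cavity). The
  asymmetric rate is solved so that the stationary binomial mixture at
  bent fraction 0.30 yields 39 crossings/µs ≈ 6.25 pA, the scale of the
  fastest membranes; the all-bent rate of 18/µs corresponds to ≈ 2.9 pA.
  Crossings are smooth 2 ns ramps through the filter slab so events are
  unambiguous at the default 0.1 ns/frame;
* two lipid phosphate layers at ±thickness/2 and isotropic Gaussian
  positional noise (default σ = 0.01 nm on protein atoms).

Presets plant the three observed membrane groups and the all-bent channel
by varying only the gating rates (hence `f_bent`: 0.30, 0.125, 0.03, 1.0)
and the membrane thickness (3.6, 3.5, 4.6, 3.9 nm) while sharing the one
crosstalk map — membranes shift the conformational equilibrium; the
channel's conduction map is a property of the channel.

An equilibrium-ion mode replaces crossings by i.i.d. Boltzmann sampling of
ion z positions from exp(−U) for a user potential U(z), which gives the
profile machinery an exact oracle (inverse-CDF sampling on a 0.002 nm
grid).

What the generator does **not** emulate: real backbone covalent geometry,
water structure, knock-on multi-ion permeation, state-dependent dwell of
ions in S1–S4, cooperative gating between subunits (chains are
independent; a coupling hook exists), membrane undulations, or any force
field physics. Passing tests therefore demonstrate that the *analysis
machinery* is correct and self-consistent at desk scale — they cannot
validate conclusions about real MD data, and headline values from
hundreds of microseconds of all-atom simulation are far outside what this
package regenerates.

## Problem sizes and numerical choices

The test suite and the acceptance script run synthetic ensembles of 8
replicates × 3000 frames (0.1 ns/frame, i.e. 0.3 µs/replicate) per preset
for ensemble-level statistics, 10⁵ Boltzmann samples for profile
inversion (recovery to ≤ 0.15 kBT RMS on bins with ≥ 100 counts), and
20 000-frame chains for stationary-fraction checks — sizes chosen so the
statistical tolerances derived from Poisson/binomial counting are tight
while a full run stays interactive. Statistical assertions use 3σ bands
computed from the planted rates (with the two-state integrated
autocorrelation time 1/(k_kb+k_bk) correcting the effective sample size);
geometric assertions use the documented format precisions (10⁻⁴ nm for
PDB text, ~10⁻⁵ nm for float32 DCD).

Tie-breaks and degenerate inputs are all explicit: first-frame
classification ties go to kinked; empty selections warn rather than fail;
empty pore slices return r_max flagged; a single replicate reports SEM as
missing; monolayers, triclinic boxes, glycine "side chains" and
heavy-atom-only hydrogen-bond requests raise targeted errors.

## Known limitations

* Trajectory formats are DCD and multi-model PDB (plus PDB/GRO
  topologies). XTC is not supported: no R-side reader for the XDR
  compressed format is available to build on, and a hand-rolled one would
  be the least trustworthy part of the stack.
* Frame times are reconstructed from a user-supplied `dt` because neither
  format carries reliable time stamps.
* The pore-radius profile is slice-based, not a propagating-sphere HOLE
  computation; for strongly off-axis pores enable the per-slice centre
  optimization.
* The event detector tracks ions by unwrapped z only; xy excursions are
  ignored for crossing detection (the filter is narrow), while site
  occupancy does apply an axial-radius criterion (default 0.4 nm).
* `analysis/` scripts and the acceptance script regenerate everything
  from seeds; there is no caching layer.
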