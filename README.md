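# kinkgate

Trajectory analysis of **two-gate crosstalk** in tetrameric potassium
channels (MthK-like), for structural biologists and simulators who want to
go from a topology + trajectory to the numbers behind a gating story:
which subunits are kinked or bent, how open the selectivity-filter gate
is, where the Phe87 side chains point, how many ions crossed, and how all
of that fits together.

## The science in one paragraph

The pore-lining inner helix of MthK switches between a **kinked** state
(broken Val81–Gly85 / Leu82–Thr86 backbone H-bonds, bending angle ≈ 43°,
closed filter entrance) and a **bent** state (H-bonds formed, ≈ 30°, open
filter entrance but Phe87 rotated into the central cavity). The lipid
environment shifts this equilibrium, and the equilibrium sets the ion
current through two coupled gates: the Thr59 Oγ ring at the filter
entrance opens with the bent-state fraction *f*<sub>bent</sub>
(mean over frames and subunits of the bent indicator), while the cavity
dehydrates as more subunits go bent. Conduction therefore requires an
*asymmetric* tetramer: all-kinked is nonconductive (closed filter),
all-bent is nonconductive again (dehydrated cavity). Currents come from
counting full filter traversals, `I = (n⁺ − n⁻) e / t`, under a
constant-field voltage `V = E × L` (0.0325 V/nm × 9.2308 nm = 300 mV).

The package implements, per module: topology/trajectory I/O with a small
selection language (`load_topology`, `read_frames`, `select`); the gating
descriptors and a hysteresis state classifier (`hbond_distance`,
`bending_angle`, `classify_state`, `cross_subunit_distance`,
`phe87_cof_distance`, ...); permeation counting and currents
(`filter_bounds`, `detect_permeation_events`, `current_from_events`,
`site_occupancy`); axial density/"free energy", pore-radius and
membrane-thickness profiles; PLS functional mode analysis (`superpose`,
`fit_fma`, `extreme_conformations`); a fully ground-truthed synthetic
trajectory generator (`synthetic_spec`, `generate_trajectory`,
`preset_conduction_group`); and ensemble reporting (`run_ensemble`,
`split_replicates`, `correlate`, `config_resolved_conductance`).

## Worked example

Generate one replicate of the fast-conducting membrane preset and analyze
it end to end:

```r
library(kinkgate)
spec <- preset_conduction_group("high_current", n_frames = 3000L)   # 0.3 us
gen  <- generate_trajectory(spec, seed = 1)
a    <- analyze_replicate(gen$topology, gen$frames)
a$summary[, c("f_bent", "I_pA", "n_plus", "d_ogog", "d_cof", "thickness")]
#>      f_bent    I_pA n_plus    d_ogog     d_cof thickness
#> 1 0.3986667 9.61306     18 0.5162581 0.7682922  3.600035
```

This replicate spent 40% of its subunit-frames in the bent state and
carried 18 outward crossings in 0.3 µs (9.6 pA — a single short replicate;
the 8-replicate ensemble mean sits near the planted 6.25 pA scale). The
Thr59 Oγ–Oγ distance (0.516 nm) sits between the all-kinked (0.497 nm) and
all-bent (0.533 nm) limits, and the mean Phe87-CoF distance (0.77 nm) is a
mixture of the out-of-cavity (0.836) and in-cavity (0.666 nm) orientations.

The crosstalk itself, resolved by tetramer configuration:

```r
config_resolved_conductance(a$states, a$events, dt = 0.1)
#>   n_bent n_frames residence_fraction n_events rate_per_us
#> 1      0       60          0.0200000        0     0.00000
#> 2      1     1333          0.4443333        7    52.51313
#> 3      2     1370          0.4566667       10    72.99270
#> 4      3      237          0.0790000        1    42.19409
#> 5      4        0          0.0000000        0          NA
```

No crossing happened while the tetramer was all-kinked; the asymmetric
1–2-bent configurations carried essentially all the current (planted
rate: 54.7 events/µs for those configurations, 0 for all-kinked).

The numbered scripts under `analysis/` run the same machinery as a
narrative workflow — generation, conformation, permeation, profiles, FMA,
ensemble report — writing their tables to `results/`.

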