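---
title: "Mesoscale simulation of pentablock terpolymer self-assembly: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mesoscale simulation of pentablock terpolymer self-assembly: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pentadpd)
```

## The physical model

`pentadpd` simulates amphiphilic pentablock terpolymers in explicit solvent
with dissipative particle dynamics (DPD).  A chain is the symmetric linear
sequence C–B–A–B–C: `nC` beads of species C at each free end, `nB` beads of
B on either side, and `lA` beads of A in the centre
(`chain_topology(nC, nB, lA)`); the reference chain is C3B3A6B3C3, eighteen
beads.  Solvent is a fourth species, S.  All quantities are in reduced DPD
units: the pair-interaction cutoff `rc` is the length unit, `kBT` the energy
unit, and every bead carries mass 1 (the conventional DPD choice; no bead
mass is otherwise specified by the model), so the time unit is
`rc * sqrt(m/kBT)`.

Between every bead pair within the cutoff act three pairwise forces:

* a soft conservative repulsion `F_C = a_ij (1 - r/rc) e`,
* a dissipative drag `F_D = -gamma (1 - r/rc)^2 (v_ij . e) e`,
* a random kick `F_R = sigma (1 - r/rc) xi dt^(-1/2) e`, with one
  zero-mean, unit-variance draw `xi` shared symmetrically by the pair each
  step.

The dissipative and random weights obey `omega_D = omega_R^2`, and the
amplitudes obey the fluctuation–dissipation relation
`sigma^2 = 2 gamma kBT`; together these make the pair a momentum-conserving
thermostat.  The package never lets `gamma` be set directly:
`dpd_params()` derives it from `sigma`, so the relation holds by
construction.  Defaults are `sigma = 3` (hence `gamma = 4.5` at `kBT = 1`),
bead density `rho = 3`, timestep `dt = 0.04`.

Bonded neighbours along a chain feel a harmonic spring
`F_S = -C (r - r_eq) e` with `C = 8` and `r_eq = 0`; with a zero rest
length this is a linear attraction of magnitude `C r`.

The conservative amplitudes live in a symmetric 4x4 matrix over
`{A, B, C, S}` (`interaction_matrix()`).  The diagonal is `a_ii = 25`
(appropriate for density 3), all polymer–polymer cross pairs share
`aAB = 40` (weak inter-block segregation), the B–solvent amplitude is
`aBS = 45`, and the two control parameters `aAS` and `aCS` set the solvent
selectivity toward the centre block and the end blocks.  Amplitudes map to
Flory–Huggins incompatibilities through `a_ij = a_ii + 3.27 chi_ij`
(`a_to_chi()` / `chi_to_a()`).  Scanning `aAS` and `aCS` over roughly 26 to
105 at a polymer volume fraction of 10% drives the system through a state
diagram of layered and onion-like micelles, unilamellar and onion-like
vesicles, vesicle-in-vesicle structures, planar lamellae, and a dispersed
("disordered") melt.

## Integrator and thermostat implementation

The engine advances the system with the lambda-modified velocity-Verlet
scheme standard in DPD work (`lambda = 0.5`): positions advance with the
current force, a predicted velocity `v + lambda dt f` enters the
dissipative force at the new positions, and the velocity is corrected with
the mean of old and new forces.  After the correction the dissipative force
is re-evaluated at the corrected velocity, so the force carried into the
next step is a pure function of the current state and step index.  Two
consequences matter in practice: checkpoint restarts are bit-exact, and the
measured kinetic temperature at `dt = 0.04` sits within about one percent
of the target (the suite asserts 5%).  The plain velocity-Verlet variant
would shift the temperature artifact by a few percent; the lambda-modified
scheme with re-evaluation was chosen because it keeps that artifact small
at the production timestep.

The random draw `xi` is uniform on `[-sqrt(3), sqrt(3)]` (zero mean, unit
variance) by default, with a Gaussian variant behind the `gaussian`
switch; with the soft DPD potential both sample the same equilibrium
ensemble and the uniform draw is cheaper.  Draws come from a counter-based
hash keyed on `(seed, step, min(i,j), max(i,j))` rather than a sequential
generator.  This guarantees `xi_ij = xi_ji` exactly, makes the stream
independent of pair-traversal order — so the cell-list path and the
all-pairs reference path consume identical noise and can be compared to
`1e-12` — and keys restarts to the absolute step index.

Pair search uses a linked-cell list with cell edge at least the cutoff.
For untilted boxes a half-stencil cell-pair sweep visits each unordered
pair once; for tilted (sheared) boxes the stencil is widened along the
shear axis for image rows and duplicate cells are suppressed with a stamp
array, so very small boxes degrade gracefully to an all-pairs scan rather
than double counting.  Within the pair search the periodic image is
selected by coordinate rounding, which is exact for any pair closer than
half the smallest box edge; the exhaustive 27-image search remains the
reference implementation for arbitrary displacement queries
(`minimum_image()` and the test oracles).

Coincident beads (zero separation) have no defined force direction; the
potential is soft and finite there, so the engine applies zero force and
counts the event, and the R layer warns once per evaluation.

## Bulk shear

Shear is applied through Lees–Edwards sliding-brick boundaries at constant
strain rate (default `0.001` in the production protocol, plane `xz`): each
step the tilt offset of the +z image row grows by `rate * Lz * dt`,
cumulative strain grows by `rate * dt`, and the offset is re-wrapped into
`(-Lx/2, Lx/2]` without touching the strain account (strain is offset over
the perpendicular box length, accumulated).  Pairs interacting across the
z boundary see both the displaced image position and the image velocity
offset `rate * Lz`, and a bead crossing the boundary has its x coordinate
and x velocity shifted accordingly.  The thermostat therefore acts on total
relative velocities including the flow, and no profile subtraction is
needed: the pairwise thermostat is Galilean invariant and the linear
Couette profile emerges physically from boundary momentum transfer.  The
acceptance suite measures that emergent profile in a tall solvent column
(10 x 10 x 20, chosen because slope precision scales with the variance of
the gradient coordinate at fixed cost) and finds the slope within 20% of
the applied rate; the kinematic identities (offset increment, cumulative
strain, tilted minimum image) are exact.

An alternative implementation — remapping all positions affinely with the
deforming box each step — represents the same physics in co-deforming
coordinates, but leaves peculiar velocities flow-free, which would make the
emergent-profile check vacuous.  The sliding-brick convention was chosen so
that the flow is observable in the stored velocities.

## System construction

`build_system()` fills a periodic box at `round(rho V)` beads: the chain
count is the nearest integer to `phi N / chain_length` (the achieved
polymer fraction is therefore within one chain of the request and is
recorded in the returned frame), chains are placed as random walks with
step length near `0.7 rc` (the typical equilibrium bond length under the
soft potential), and the remainder is solvent.  DPD potentials tolerate
overlaps, so no minimisation is needed and runs start from this homogeneous
state.  `init_velocities()` draws Maxwell–Boltzmann velocities, removes the
net momentum exactly, and rescales to the requested temperature using
`3N - 3` degrees of freedom.

## Synthetic aggregates with ground truth

The fixture builders construct idealized equilibrium structures so that
every analysis operator can be validated against labels known by
construction, without long simulations:

* `make_unilamellar_vesicle()` — concentric spherical shells C/B/A/B/C
  around a cargo-filled cavity, exterior solvent outside;
* `make_onion_vesicle()` — multiple concentric membranes (default
  A/B/C/B/A) separated by solvent gaps, optional solvent co-located in the
  hydrophilic shells (the S-peaks-on-A-peaks signature), degenerating to a
  solvent-free onion micelle;
* `make_planar_bilayer()` — an A/B/C/B/A slab spanning the box.

Regions are populated by uniform random sampling at the model density, so
analysis operators never see crystalline placement.  Uniform sampling
occasionally leaves a bead disconnected from its region; a repair pass
re-draws such strays until each constructed region is single-linkage
connected, because an isolated exterior solvent bead would otherwise read
as a spurious cargo pocket.  Fixtures are deterministic under a fixed seed
and carry their construction parameters and per-bead region labels as a
`ground_truth` attribute.

What the fixtures deliberately do not emulate: thermal interface roughness,
composition interdigitation between leaflets, solvent penetration profiles,
and equilibrium shell spacing.  Passing the fixture suite therefore
demonstrates that the measurement operators recover known geometry and
labels — not that the dynamics produces those geometries; that is what the
reduced-scale simulation checks are for.

## Analysis definitions

**Aggregates.**  `find_aggregates()` clusters polymer beads.  Bonded beads
always share a cluster (a chain is one molecule).  Two molecules merge when
they share at least `min_contacts = 3` bead contacts closer than
`cutoff = 0.8 rc`.  Both defaults deserve comment, because the obvious
alternative — plain single linkage at the interaction range `rc` — fails
qualitatively at liquid density: every bead has many neighbours within
`rc`, and chains that are merely dispersed in solvent chain up into
spanning pseudo-clusters.  The contact distance `0.8 rc` is the first-peak
scale of the pair correlation function at density 3, and the three-contact
rule demands a persistent interface rather than a grazing touch (the
threshold is capped by the smaller molecule's bead count, so single-bead
"molecules" — e.g. fixture beads, which carry no bonds — reduce to plain
single linkage).  With these definitions a weakly-interacting melt at
`aAS = aCS = 26` resolves into many small transient clusters (largest well
below half the polymer), while condensed micelles and vesicle membranes,
whose interiors sit at density 3, remain single clusters under any contact
distance down to the bond length.  Each cluster records whether it is
connected to its own periodic image (detected by image-offset bookkeeping
along a BFS spanning tree); a wrapping cluster spans the box — the lamella
signature.  Cluster centres are circular-mean averages per fractional
coordinate, exact for compact clusters under periodic boundaries.

**Composition profiles.**  `composition_profile()` bins all beads (solvent
included) by minimum-image distance from an aggregate centre (default bin
`0.25 rc`, the resolution at which the reference profiles are drawn) and
reports per-bin species number fractions, which sum to one; empty bins are
absent, not zero, and all band logic treats a radial gap as a band break.

**Encapsulated cargo.**  `encapsulated_solvent()` clusters solvent at the
interaction range `rc` (solvent at density 3 percolates robustly at this
distance, so pockets are genuine cavities rather than sampling noise) and
classifies a cluster as exterior exactly when it connects to its own
periodic image in some dimension.  Encapsulated solvent is whatever solvent
does not percolate.  This inside test is geometry-free: it needs no sphere
fit, works for deformed vesicles, and hands each cavity of a
vesicle-in-vesicle its own pocket.  `release_timeseries()` then reports,
per frame, the fraction of an initial cargo set that is still encapsulated;
cargo (S0) tags are bookkeeping only and never enter forces.

**Connectivity.**  `interconnected_count()` measures hydrophilic membrane
connectivity: same-species beads within `rc` are connected, seeds are the
beads of the innermost radial band where the species fraction exceeds
0.25, and the result reports the reachable count `n`, the seed count
`n_i`, the species total `n_max`, and whether the outermost band was
reached (`linked`).  By default it analyses all polymer in the frame about
the polymer centre of mass, because the concentric membranes of an onion
vesicle are disjoint clusters separated by solvent yet belong to one
structure.  The band threshold, connection cutoff and shell ranges are
returned with the result so every decision is auditable.

**Membrane thickness.**  `membrane_thickness()` takes the combined
hydrophobic fraction, finds the contiguous band above 0.5 with the largest
integrated bead count, and interpolates the two 0.5 crossings linearly
between bin centres; a band touching the profile edge (or a radial gap) is
bounded by the bin edge.  On fixtures this recovers constructed widths
within one bin.

**Morphology.**  `classify_morphology()` walks a fixed decision tree:
dispersed melt (largest cluster under half the polymer), lamella (largest
cluster wraps), then — when encapsulated solvent exists — onion vesicle
(two or more concentric membrane bands), vesicle-in-vesicle (single band
but two or more pockets), else unilamellar vesicle; without encapsulated
solvent, the radial ordering of dominant species over polymer-dominated
bins separates onion-like micelles (three or more species bands), layered
micelles, and irregular spheres.  Every label carries an `evidence`
attribute with the quantities and thresholds used.

## Problem sizes and what the checks mean

The suite runs at deliberately reduced scale, chosen as the smallest
systems in which each claim is statistically meaningful:

* thermostat fidelity: 375 solvent beads (5^3 box), 10^4 steps, temperature
  averaged over the second half; momentum drift stays below 1e-8 per
  component;
* force-path equivalence: cell list versus all-pairs at 1e-12 on ~200
  beads, with and without tilt; a bonded two-bead oscillator matches its
  closed-form period within 1%;
* shear: kinematic identities exact; the emergent Couette slope is measured
  in a 10 x 10 x 20 column over 3.5x10^4 sampled steps after a 9x10^3-step
  transient (the transient covers the momentum-diffusion time over half the
  column height), expected statistical error about 6%, asserted within 20%;
* dispersed-melt behaviour at `aAS = aCS = 26`: a 10^3 box (about 34
  chains) keeps cluster statistics out of the few-chain regime; in an 8^3
  box the same check is bimodal purely by finite size;
* reduced self-assembly at `aAS = 26, aCS = 45` (solvent favouring the
  centre block): a 12^3 box at 10% polymer condenses within 6x10^4 steps
  into a single concentric aggregate whose hydrophobic (B+C) band thickness
  sits at the reference scale of about 2.7 rc.  At this box size the
  aggregate is the smallest concentric unit (one membrane); the full
  multi-lamellar onion and the production state diagram require
  cluster-scale boxes and step counts and are outside the test envelope.

The hydrophilic-C vesicle condition (`aAS = 65, aCS = 26`) needs
substantially more chains before a membrane can close around a cavity: in
boxes up to 14^3 the melt forms compact layered micelles with no interior
solvent.  `scripts/extended_spot_checks.R` runs that condition at 16^3 and
beyond; it is a long-running companion script, not part of the default
suite.

## Numerical edge cases

* Zero-separation pairs: zero force, counted, warned once per evaluation.
* `n_steps = 0`: the input frame is returned unchanged.
* A single bead cannot satisfy both zero momentum and a target temperature;
  velocity initialisation refuses it.
* Tilt re-wrapping by a full box length never changes pair distances or
  strain; all analyses are invariant under global translation and
  re-wrapping of coordinates (asserted in the suite).
* Text frames store positions at `%.6f`; checkpoints store positions and
  velocities at `%.17g` plus the absolute step index, which (with the
  counter-based noise) makes a restart continue the interrupted run
  bit-exactly.

## Known limitations

* The engine is single-threaded and rebuilds its cell list every step; a
  Verlet-skin pair cache would roughly halve the cost of sheared runs but
  is not implemented.
* Only the `xz` shear plane is supported; rotate the configuration for
  other planes.
* Morphology labels at very small box sizes are finite-size limited (few
  chains), as quantified above; labels should be read together with their
  evidence record.
* The production protocol of the field (multi-million-step equilibration,
  tens of thousands of beads) is far beyond the test envelope; the package
  reproduces definitions, mechanics and reduced-scale behaviour, and scales
  to production sizes only with correspondingly long wall-clock times.
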