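---
title: "Methods: desk-scale MD screening of drug-polymer dispersions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: desk-scale MD screening of drug-polymer dispersions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope and model

`dispermd` implements, at desk scale, the computational workflow used to
screen active pharmaceutical ingredients (APIs) against polymeric excipients
for amorphous solid dispersions: build an API/polymer mixture box, run short
molecular dynamics, and rank excipients by the statistics that predict
miscibility — the time-averaged API–polymer interaction energy decomposed
into electrostatic and Lennard-Jones parts, the energy ratio
E_total(API–polymer)/E_total(API–API), and geometric hydrogen-bond counts —
supplemented by radial distribution functions, mean-squared displacement
(MSD), and crystal density/lattice validation.

The potential is an OPLS-style model:

* nonbonded: Lennard-Jones `4*eps*((sig/r)^12 - (sig/r)^6)` plus Coulomb
  `f*qi*qj/r` with `f = 138.935458 kJ mol^-1 nm e^-2`, geometric combining
  rules for both `sigma` and `epsilon`, 1-2/1-3 exclusions and 1-4 pairs
  scaled by 0.5 (the standard OPLS convention; the emulated protocol names
  the force-field family but not the rules);
* bonded: harmonic bonds `0.5*k*(r - r0)^2` and harmonic angles
  `0.5*k*(theta - theta0)^2`; cosine dihedrals are not implemented — the
  packaged toy templates do not need them and torsional barriers are beyond
  what desk-scale screening statistics resolve.

All internal quantities are nm / ps / kJ mol^-1 / K / e; every file reader
converts at the boundary (PDB and XYZ are Angstrom, GRO is nm). Cutoff
distances quoted in Angstrom by the protocol (14 A for LJ, 3.5 A for
hydrogen bonds) are converted once when configurations are built.

## Electrostatics: a documented deviation

The emulated protocol uses particle-mesh Ewald electrostatics. A mesh Ewald
solver is deliberately out of scope here: group-wise energy decomposition —
the screening statistic itself — is only defined for pairwise real-space
terms, which a reciprocal-space sum cannot provide either. The engine
therefore uses a Coulomb cutoff with an energy shift at `r_c` (potential
continuous at the cutoff), and a plain Ewald sum (`ewald_energy()`, real +
reciprocal + self, no mesh, energy only, systems up to 3000 atoms) is
provided as an independent cross-check; the test suite verifies it against
the NaCl Madelung constant to 2e-4. LJ interactions are plainly truncated
at 1.4 nm by default (no long-range dispersion correction, matching the
protocol's silence; a homogeneous tail correction is available behind
`cutoff_scheme(dispersion_correction = TRUE)`). Pairs at exactly `r = r_c`
are included — a deterministic tie-break. Toy-scale mixture boxes are often
smaller than twice the 1.4 nm cutoff; the pipeline then uses 0.9 nm and the
minimum-image requirement (box >= 2 cutoff) is always enforced as an error.

## Engine

* Steepest-descent minimization with adaptive step halving; energy is
  non-increasing across accepted steps, convergence at a maximum atomic
  force of 1000 kJ/mol/nm (the protocol's threshold).
* Maxwell–Boltzmann velocities at the target temperature, centre-of-mass
  momentum removed, then rescaled so the kinetic temperature with
  `3N - 3` degrees of freedom is exact.
* Leap-frog integration, default `dt = 2 fs`. Reported kinetic energies
  average the two adjacent half-step values, removing the leading
  O(dt^2) bias of half-step velocities.
* Thermostat: stochastic (canonical-sampling) velocity rescaling with
  `tau = 0.1 ps` — "velocity rescale" in modern MD denotes this variant;
  a plain Berendsen rescale is available for comparison
  (`thermostat_config(type = "berendsen")`). Centre-of-mass motion is
  removed every step in thermostatted runs to prevent flying-ice-cube
  artifacts.
* Barostat: isotropic weak coupling on orthorhombic boxes. Anisotropic
  cell scaling is not implemented; for non-cubic crystals this would bias
  individual lattice parameters, which is why the packaged crystal
  validation uses a cubic toy solid and external (user-supplied) crystal
  runs should treat lattice-parameter anisotropy with caution.
* Neighbour search: pair list built by linked-cell binning with a 0.2 nm
  skin, rebuilt when any atom has moved more than half the skin. The list
  path and the O(N^2) path agree to better than 1e-9 relative (exact
  pair set, different summation order only).

The integrator is validated by properties rather than trajectories: NVE
total-energy drift below 0.01 kJ/mol/atom per 100 ps at `dt = 1 fs` on a
200-atom LJ fluid; NVT mean kinetic temperature within 3 canonical standard
deviations of the target at 300/373/433 K with variance in a factor-2 band
of `2T^2/N_df`; dimer oscillation periods against the harmonic closed form;
an ideal-gas NPT density against `P*M/(R*T)`.

## Synthetic systems: what the generator emulates

The study's real inputs (CCDC crystal structures, vendor-built polymer
chains, OPLS-AA parameter files) are not redistributable, so the generator
ships coarse, chemically plausible archetypes — explicitly *not*
reparameterizations of the real molecules:

* four APIs: a neutral aromatic acid (ring + COOH + methyl, ~18 atoms), an
  ionic pair (glycinate-like anion, net −1, with N–H donors, plus an
  unbonded Na+ counter-ion in the same molecule), a small neutral methyl
  ester (acceptors only), and a donor-rich amide-alcohol;
* three excipient monomers (acrylic-acid-like, polar-ester-like,
  acetate-like), each with head/tail link carbons; chains are built as
  repeat units (10 monomers by default, so chain mass is exactly 10 monomer
  masses), laid on a gentle arc and relaxed in vacuum.

Partial charges were chosen once, at design time, so the archetypes embody
the qualitative chemistry the screening statistics must distinguish: the
ionic API's interactions are dominated by electrostatics and it forms the
most hydrogen bonds per molecule, while all three neutral APIs are
dominated by dispersion. The neutral templates carry deliberately diluted
polar charges because a 10–20-atom toy molecule has a far larger *polar
fraction* than a real 30-atom drug; without that dilution the toy world
would contradict the chemistry it is meant to emulate.

Mixture boxes: the number of chains for a target API weight percent `w` is
`round(n_api*M_api*(100-w)/(w*M_chain))` (an unreachable composition is an
error), so the achieved loading differs from the target by less than one
chain mass over the total mass. Molecules are inserted with seeded uniform
random positions/orientations under a hard 0.2 nm heavy-atom clash radius.
Random insertion only works at gas-like densities, so boxes are packed at
<= 0.35 g/cc and then densified to the target (default 0.75 g/cc, a loose
melt — real amorphous dispersions are ~1.2–1.3 g/cc, but toy force fields
at toy durations equilibrate poorly at full density) by alternating 3%
isotropic contractions with steepest-descent relaxation. All generators are
deterministic given a seed.

Crystal supercells replicate a `unit_cell_spec` (crystallographic
Angstrom/degree convention, `Z` formula units, molar mass, fractional
contents) exactly; density is invariant under replication by construction.
The packaged crystal is a *synthetic* FCC Lennard-Jones solid
(`toy_crystal_cell()`), deep-welled enough to stay solid at 300 K.

## Analysis conventions

* **Group interaction energies** sum plain (unshifted) real-space LJ +
  Coulomb pairs within the cutoff, minimum image, topology exclusions
  honoured; self-interaction (API–API) excludes intramolecular pairs at
  molecule granularity, with `include_intramolecular = TRUE` exposing the
  counter-ion/anion contribution of the ionic archetype. Frames are
  weighted uniformly over the analysis window (by default the last 80% of
  the run, mirroring the discard-first-20% convention) and the standard
  error is block-averaged with 5 blocks. Energies are reported both as
  system totals and per API molecule, since reporting conventions differ.
* **Energy ratio**: E_total(API–polymer)/E_total(API–API), defined when
  both are attractive and the denominator exceeds 1 kJ/mol in magnitude;
  otherwise flagged invalid with a reason rather than raising. At desk
  scale API–API contacts are rare at 5 wt%, so toy ratios can far exceed
  the 0–2.2 range seen in the full-scale study; only their *directions*
  across loadings and temperatures are asserted.
* **RDF** follows the shell-count normalization
  `g(r) = N_ij(r, r+dr) * V / (4 pi r^2 dr N_i N_j)` with ordered pairs
  (j around i), default `dr = 0.02 A` and `r_max` = half the smallest box
  dimension. Intramolecular pairs are *included* by default because the
  reference same-species profiles peak at bonded distances (~1 A); an
  intermolecular-only mode is a flag. Which mode the original analysis
  used is ambiguous, so neither is asserted against the published curves.
* **Hydrogen bonds**: donor–acceptor distance <= 3.5 A *and*
  hydrogen–donor–acceptor angle (vertex at the donor heavy atom, exactly
  as stated) <= 30 degrees, both boundaries inclusive (implemented on the
  cosine with a 1e-12 tolerance so exactly-constructed boundary geometries
  count). Donors are O–H/N–H hydrogens, acceptors any O/N, both derived
  from topology and overridable per atom.
* **MSD** uses molecular centres of mass on unwrapped coordinates. The
  time average is read as a sliding-origin average by default
  (`origin_mode = "multi"`); `"single"` reproduces the literal
  origin-at-window-start reading. The diffusion coefficient is the fitted
  slope/6 (Einstein relation) with an R^2-based ballistic-regime flag.
* **Crystal metrics** average density and per-frame lattice parameters
  over the window, divide by the replication counts, and report
  `100*(sim - ref)/ref` per quantity with a <3% pass flag.

## Study designs

`run_screening_matrix()` crosses every API archetype with every excipient
at 5 wt% and 300 K and ranks excipients per API by most-negative E_total
(ties: larger energy ratio, then more hydrogen bonds). `run_loading_study()`
compares 5 vs 50 wt%; `run_temperature_study()` sweeps 300/373/433 K at
50 wt% (the composition context of the original temperature analysis).
Every run is derived from a serializable plan plus a seed; reports carry
the plan hash and seeds, and rerunning with the same seeds reproduces the
report bit-for-bit.

A design choice worth flagging: the loading study holds the *simulation
cell* fixed across loadings (sized for the 5 wt% composition at the plan
density), mirroring the constant-volume construction of the emulated
protocol, where higher loading means fewer chains in the same box. The
50 wt% system is therefore less dense, and its higher API mobility partly
reflects that dilution — at matched density the desk-scale MSD contrast is
within noise, which is an honest limitation of 10-ps toy trajectories. The
energy and energy-ratio trends do not depend on this choice (both also hold
at matched density).

## What a green test establishes — and what it does not

The acceptance suite checks (1) the published density worked examples from
lattice parameters, Z and molar mass to 0.01 g/cc; (2) the crystal
validation machinery (exact at zero dynamics, <3% on a short toy-solid NPT
run); (3) engine statistical properties; (4) exact/1e-9 agreement of every
analysis kernel with independent brute-force recomputation; (5) the
*directions* of the screening mechanisms on the packaged archetypes over
three seeds; (6) hydrogen-bond boundary behaviour exactly as printed.

Green tests do **not** establish chemical accuracy for any real
API-excipient pair: the archetypes are statistical stand-ins, runs are
~10 ps rather than 10 ns, electrostatics are cutoff-based, and the
excipient rankings produced for toy species have no bearing on real
formulation choices. Users with real OPLS-AA parameter sets can supply them
through the topology format and run the identical analysis stack.

## Numerical choices

Bond force constants are 1e5 kJ/mol/nm^2 (heavy-heavy) and 5e4 (X–H) so
that the stiffest oscillation period stays ~10x the 2 fs step without
constraints; angle constants are 300 kJ/mol/rad^2; template geometries are
their own bonded-term minima. The minimizer starts with 0.01 nm steps,
grows them 1.2x on success and halves on failure. Energy divergence beyond
1e6 kJ/mol per atom aborts with a diagnostic. Seeds for sub-stages
(packing, velocities, thermostat noise) are derived from the run seed by a
fixed affine map kept below 2^31.
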