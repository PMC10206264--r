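---
title: "Binding-model analysis and R-group design with bindsight"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binding-model analysis and R-group design with bindsight}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bindsight)
```

## What the package computes

`bindsight` analyses protein–ligand molecular dynamics trajectories with the
standard end-state recipe and turns the result into a combinatorial inhibitor
design. The chain is:

1. **Stability and contacts** — RMSD/RMSF, distance/angle monitors, and
   hydrogen-bond occupancy over the trajectory.
2. **MM/GBSA binding free energy** — frame-averaged interaction enthalpy with
   a generalized-Born polar term and a surface-area nonpolar term, minus a
   configurational entropy estimate.
3. **Per-residue decomposition** — attribution of the binding enthalpy to
   individual residues, split into backbone and side-chain parts, with a
   0.50 kcal/mol key-residue threshold.
4. **Trajectory clustering** — average-linkage clustering on pairwise RMSD;
   the medoid frame of each cluster becomes a rigid receptor for ensemble
   scoring.
5. **Four-region R-group design** — one-region modification libraries, top-k
   group selection per region, full cross-combination with positional
   `C{r1}{r2}{r3}{r4}` naming, named variants, and min-over-ensemble score
   aggregation with a −10.00 kcal/mol shortlist threshold.

The worked system throughout is an ATP-competitive kinase inhibitor bound to
a CDK6-like receptor: the hinge-loop hydrogen bonds anchor the scaffold, and
four substitution regions (R1–R4) around it are varied.

## The MM/GBSA model

For each frame of the complex trajectory, receptor and ligand coordinates are
taken from the *same* frame (single-trajectory protocol), so intramolecular
bonded terms cancel exactly in the delta and are never computed. The per-frame
delta terms are

$$\Delta E_{gas} = \Delta E_{vdW} + \Delta E_{ele}, \qquad
  \Delta E_{solv} = \Delta E_{GB} + \Delta E_{surf},$$

$$\Delta G = \underbrace{\langle \Delta E_{gas} + \Delta E_{solv}\rangle}_{\Delta H}
  - T\Delta S .$$

These identities are maintained by construction in `energy_breakdown()` and
`binding_free_energy()`, so the accounting (polar = $E_{ele}+E_{GB}$,
nonpolar = $E_{vdW}+E_{surf}$) is exact whatever the inputs.

* **vdW / electrostatics** — Lennard-Jones 12-6 with Lorentz–Berthelot
  combination; Coulomb with constant 332.0637 kcal·Å/(mol·e²) and interior
  dielectric 1. No distance cutoffs: the systems handled here are desk-scale,
  and cutoffs would break the separation-limit property (all deltas → 0 as
  the ligand is pulled to infinity) that the tests assert.
* **Generalized Born** — the Still pairwise form with OBC-II effective radii
  (α = 1.0, β = 0.8, γ = 4.85, offset 0.09 Å), ε_in = 1, ε_out = 78.5, zero
  salt. These are the common defaults of the standard MM/GBSA tooling; an
  isolated ion reduces to the analytic Born energy at its effective radius,
  which the tests check to 1 × 10⁻⁶ relative.
* **Nonpolar term** — $E_{surf} = 0.0072 \cdot \mathrm{SASA} + 0$, with
  solvent-accessible areas from a deterministic Shrake–Rupley sampler
  (golden-spiral sphere points, default 960; the isolated-sphere error at 960
  points is below 1%). A deterministic point set keeps every energy bitwise
  reproducible.
* **Entropy** — quasi-harmonic: eigenvalues of the mass-weighted coordinate
  covariance define harmonic modes whose quantum-oscillator entropies are
  summed. Externally computed $T\Delta S$ values can be passed through
  `average_binding_energy(entropy = ...)` so the ΔG assembly is testable
  independently of the estimator.

### Quasi-harmonic entropy: numerical choices

By default frames are superposed onto their mean structure and the six
smallest modes are discarded as residual rigid-body motion. The closed-form
validation uses i.i.d. isotropic harmonic wells
(`generate_harmonic_trajectory()`), which have *no* rigid-body component, so
the tests call the estimator with `fit = FALSE, drop_modes = 0` and compare
against the exact $3N$-mode oscillator entropy (within 2% at 8,000 frames).
With fewer frames than degrees of freedom the covariance is singular; null
modes are discarded with a warning rather than propagated as spurious
frequencies.

### Per-residue decomposition

Every delta term is split over residues frame by frame and then averaged:

* intermolecular vdW/electrostatic pair energies: half to each partner's
  residue, the ligand's halves pooled under a ligand pseudo-residue;
* GB: the complex's full ordered-pair energy matrix (self terms on the
  diagonal), minus the matching receptor-only and ligand-only pair energies,
  assigned row-wise — a symmetric half-split;
* surface term: per-atom SASA difference (complex minus isolated group)
  times γ, assigned to the atom's residue.

Because every pair energy is assigned exactly once, residue subtotals sum to
the delta enthalpy to machine precision; the suite asserts 10⁻³ kcal/mol.
Backbone/side-chain splits follow each atom's `is_backbone` flag (protein
backbone = N, CA, C, O plus amide H/HA; ligand atoms count as side chain).

## Hydrogen bonds and interaction classes

A donor–H…acceptor triple is bonded in a frame iff the donor–acceptor
distance is strictly < 3.5 Å *and* the acceptor–H–donor angle, vertex at the
hydrogen, is strictly > 120°. Occupancy is the percentage of bonded frames.
Strict inequalities are a deliberate choice; at the distance/angle noise
levels of real and synthetic trajectories the boundary has measure zero, so
the choice is unobservable in practice but keeps the definition unambiguous.
Donors are N/O/S atoms with an attached hydrogen (bond table first, any H
within 1.2 Å as fallback), acceptors are N/O; topology files may override
both with explicit `is_donor`/`is_acceptor` flags.

The binding-model report (`classify_interactions()`) labels residues, in
precedence order: *hydrogen-bond* (hosted occupancy ≥ 50%),
*unstable-hydrogen-bond* (occupancy 10–50%), *unfavorable* (subtotal ≥ +0.50
kcal/mol), *pi-alkyl* (subtotal ≤ −0.50 kcal/mol, mean ring–carbon contact
≤ 4.5 Å, no hydrogen bond). Only the 0.50 kcal/mol contribution threshold is
inherited from the underlying decomposition convention; the 50% / 10% / 4.5 Å
boundaries are package defaults, all exposed in the `thresholds` argument,
because no standard fixes them.

## Clustering and the receptor ensemble

The paired-frame RMSD matrix (Kabsch superposition per pair) feeds
average-linkage hierarchical clustering (`stats::hclust`), cut at the
requested cluster count. Average linkage is the common default of trajectory
analysis tools for this task; single linkage chains, complete linkage
shatters sparse basins. The representative of each cluster is its *medoid* —
the member minimizing summed RMSD to all other members — which is an actual
simulation frame, not an average structure. Clusters are relabelled by
decreasing population so `Cluster1` is always the majority basin, and frame
order never affects the result.

## The synthetic-data generator

Every stage is validated against `synthetic_spec()` complexes with known
ground truth rather than against external trajectories:

* a poly-alanine-like receptor chain (atoms N, H, CA, C, O, CB per residue,
  neutral residue charge pattern, Amber-like LJ parameters, Bondi-like Born
  radii) with a rigid multi-atom ligand hovering over the chain mid-point;
* **planted hydrogen bonds**: per frame, a seeded Bernoulli draw puts the
  triple in bound geometry (distance ≈ 2.9 Å, angle 150–180°) or unbound
  geometry (≈ 5.5 Å, 60–110°), with Gaussian distance noise constrained to
  clear the 3.5 Å threshold by 3 sd on both sides — so the planted occupancy
  is exactly the Bernoulli rate;
* **planted contacts**: the second atom of a pair repositioned along the
  reference direction to a Normal(mean, sd) distance;
* all other receptor atoms take isotropic Gaussian jitter, and the ligand
  moves rigidly by a shared translation. Atoms controlled by a planted
  feature are exempt from generic jitter; a planted acceptor on the ligand
  locally overrides ligand rigidity (three simultaneous geometric constraints
  cannot all be satisfied by one rigid motion).

Frames are drawn **i.i.d.** — a deliberate simplification of MD. That is
sufficient for estimators that are frame averages (occupancies, mean
energies, RMSF, cluster populations) but means the generator says nothing
about autocorrelation, convergence, or equilibration, and passing tests do
not certify behaviour on correlated real trajectories. Defaults (10 residues,
8 ligand atoms, 0.25 Å jitter, 200 frames) mirror the jitter scale of an
equilibrated binding-site simulation; tests use 4–8 residues and 4–2,000
frames depending on the statistical power each check needs, and energy
averages in tests run on 4–12 frames with 120–240 SASA points, which keeps
the whole suite under a minute of energy arithmetic without changing any
tested identity.

## Design stage conventions

Fragments are spliced into a scaffold template at `{R1}`…`{R4}` tokens and
canonicalized with Open Babel; an empty fragment means hydrogen and removes
its parenthesized branch. Fragment assembly is purely topological — no 3-D
conformers are generated at design time; poses are the scorer's concern.
Group indices are 1-based in the `C{r1}{r2}{r3}{r4}` naming scheme, and
`parse_compound_name()` inverts the naming exactly. Named variants (e.g. the
methylene-linker deletion that turns `C2213` into `C2213-A`) are literal,
single-use SMILES edits: applying one twice errors because the pattern is
consumed.

The packaged design library carries the published entries at their published
labels; the unnamed slots of the 42-member one-region library are filled with
plausible small substituents and **marked synthetic** in the library file, as
is every docking score that was never printed. Ensemble scores aggregate by
the minimum over receptor conformations — the established ensemble-docking
convention, and the only aggregation for which adding a receptor
conformation can never worsen a compound (a property the tests assert).
The external docking engine itself is out of scope: printed scores enter
through the table-backed scorer, and a deterministic single-point surrogate
(LJ + Coulomb with distance-dependent dielectric ε(r) = 4r + γ·ΔSASA) exists
so the full pipeline runs without any external tool. When no per-compound
pose is supplied the surrogate scores the base pose against each receptor
conformation, which differentiates receptors but not compounds — a
documented limitation, not a docking substitute.

## Known limitations

* Implicit solvent only; no Poisson–Boltzmann option, no explicit water, no
  salt screening in the GB term.
* Normal-mode entropy is not implemented; the quasi-harmonic estimate is
  known to converge slowly and to overestimate absolute entropies for
  diffusive motions. External values can be passed through.
* The decomposition's half-split convention for cross terms is one of
  several defensible attributions; comparisons across packages should use
  identical conventions.
* Region assignment is user-supplied; there is no automatic ring perception.
* The cluster count is an input, not estimated from the data.
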