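---
title: "Supercharging protein surfaces: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supercharging protein surfaces: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(superchargeR)
```

## The problem

Thermal or chemical stress partially unfolds proteins, and partially
unfolded chains aggregate — often irreversibly — through exposed
hydrophobic surface and intermolecular beta-sheet contacts. Raising the
*net* charge of the folded surface ("supercharging") makes unfolded chains
repel each other, so a supercharged variant can refold where the wild type
precipitates. The engineering question is **which surface residues to
mutate**: every charge mutation also perturbs the native structure, and
accumulating like charges or breaking surface interactions destabilizes
the folded state.

This package implements two automated answers:

1. **Exposure-ranked (AvNAPSA) protocol** — deterministic. Rank all
   candidate polar/charged residues by solvent exposure and force-mutate
   the most exposed ones until a target net charge is reached. The
   philosophy is *leave no trace*: the most exposed side chains are least
   likely to make structural contacts.
2. **Energy-guided protocol** — stochastic. Let a fixed-backbone rotamer
   packer choose mutations that improve a full-atom model energy, and
   steer how many charges it places by lowering the *reference energies*
   of the charged residue types. The philosophy is to *preserve (and
   possibly add) favorable surface interactions* while charging.

Both return the same result container (mutation list, achieved charge,
per-residue energy comparison) and the same deliverables (log, residue
file, renamed PDB), so their outputs are directly comparable.

## Surface definitions

Two definitions of "surface residue" are implemented, and either can drive
both protocols:

* **Atom-based (AvNAPSA value)** — the Average number of Neighboring Atoms
  Per Side-chain Atom: for each side-chain heavy atom, count heavy atoms
  of *other* residues within 10 Å, and average over the side chain. Low
  values mean high exposure. Glycine has no side chain and no value; it is
  never an atom-based surface member. The default surface cutoff is
  **< 120**; an extended surface uses 200.
* **Residue-based (Cβ neighbor count)** — the number of other residues
  with Cβ–Cβ distance under 10 Å (Cα for glycine). Being independent of
  side-chain conformation, it does not change as design proceeds. The
  default cutoff is **< 16**; an extended surface uses 30.

Both comparisons are strict (`<`), so a residue exactly at the cutoff is
buried. The two definitions correlate but disagree at partially buried
positions; the test suite asserts this on a seven-helix-bundle fixture.
Neighbor counting is over heavy atoms only — crystal structures usually
lack hydrogens, and a heavy-atom count keeps the metric independent of any
hydrogen-placement model. Counting includes backbone atoms of other
residues (burial by backbone is still burial) and never the residue's own
atoms.

## The exposure-ranked protocol

Candidates are all Asn/Gln plus Asp/Glu (positive polarity) or Arg/Lys
(negative polarity), sorted ascending by AvNAPSA value, ties broken by
chain and residue number. Positive supercharging mutates D/E/N/Q → K
(charge delta +2 for D/E, +1 for N/Q); negative mutates R/K/Q → E and
N → D (−2 for R/K, −1 for Q/N). Two consequences worth noting: the
protocol never designs arginine, and aspartate appears only where the
native residue is asparagine.

Selection is either the shortest prefix of the ranked list whose
cumulative charge delta reaches the target (a ±2 swap crossing the target
may overshoot by one unit; we stop at first reach-or-pass and report the
achieved charge), or — in cutoff mode — every candidate below an AvNAPSA
cutoff (historically < 150; < 100 for moderate supercharging). If the list
is exhausted first, the run fails with an `unreachable_charge_error`
carrying the best achievable charge.

Because AvNAPSA values are computed from heavy-atom counts on a fixed
backbone, mutating one residue cannot change another candidate's value, so
the ranking is computed once and never re-sorted. Forced mutations are
placed with the lowest-clash rotamer of the replacement type (smallest
model repulsion against the rest of the structure), the same side-chain
construction machinery the packer uses.

## The energy model

The packer optimizes a compact, auditable full-atom energy with the
classic fixed-backbone design decomposition. It is deliberately *not* a
re-implementation of any production score function: the protocols are the
contribution here, and they are exercised by any energy with these shapes.
All parameters live in one `energy_model()` object.

| term | form | default parameters |
|---|---|---|
| `fa_atr` | 6-12 Lennard-Jones attraction, plateau −ε inside the minimum | per-element radii C 1.70 / N 1.55 / O 1.52 / S 1.80 Å; cutoff 6 Å |
| `fa_rep` | Lennard-Jones repulsion, zero outside the minimum, linear below 0.6·r~min~ (finite clash scores) | same radii |
| `fa_sol` | burial penalty: neighbor count within 5 Å above 16 costs 0.08/neighbor for polar N/O, rewards −0.01 for C/S | models the cost of desolvating polar groups |
| `fa_pair` | ±0.5 step for charged side-chain groups within 6.5 Å, linearly switched from 5.5 Å; opposite charges negative | the knowledge-based charge-complementarity surrogate |
| `hbond_bb_sc`, `hbond_sc` | −(distance ramp)·(linearity)²; −1 at ideal geometry (2.8 Å donor–acceptor, collinear base–donor–acceptor), 0 at the 2.4/3.6 Å bounds | heavy-atom donors (N, O-H) and acceptors (O, His N) |
| `rotamer` | −ln p of the nearest library rotamer | library below |
| `reference` | per-residue-type constant | R −0.98, K −0.65, D −0.67, E −0.81; all others 0 |

All term weights default to 1. Backbone–backbone hydrogen bonds are
excluded throughout: under a fixed backbone they cannot change, so they
would only add noise to design-relevant energy differences. Interactions
between covalently adjacent residues (same chain, sequence-neighbor
numbers) are excluded from the pairwise terms — a coarse bonded-pair
(1-2/1-3/1-4) exclusion that avoids spurious clashes across the peptide
bond at template geometry.

Two deliberate omissions, shared with the score functions this model
emulates: no long-range Poisson–Boltzmann electrostatics (the pair term is
a short-range surrogate) and no cation–π term.

**Strong vs weak hydrogen bonds.** A side-chain bond with energy below
−0.5 is *strong* — the same −0.5 threshold drives the preservation rule —
and bonds in [−0.5, −0.1) are *weak*; anything shallower is counted as
numerical dust and ignored by the comparison statistics.

## Rotamer library and packing

The rotamer library is a compact backbone-independent set: canonical
gauche−/trans/gauche+ wells per rotatable chi, collapsed to at most four
of the most populated combinations per residue type, with coarse prior
probabilities that sum to one. Side chains are built from embedded
internal-coordinate templates (bond lengths/angles from standard protein
geometry) by natural extension, so no external library or download is
involved and construction is deterministic.

The **design task** marks every residue designable or preserved, with a
recorded reason: not on the surface, glycine/proline/cysteine
(`glyprocys`), already bearing the desired charge (`correct_charge`),
side chain in a strong hydrogen bond (`hbonded_sidechain`), or excluded
by the user's residue file (`resfile_excluded`). Each rule can be switched
off individually. Allowed types at designable sites are the native type —
always — plus the charged types enabled by the `include_*` flags.
Preserved side chains are fully frozen (type *and* conformation, the
conservative reading of "preserve"); the current native conformation is
always in the packer's choice set, so packing can only improve the model
energy relative to the input.

**Packing** is simulated annealing over discrete (type, rotamer) choices:
uniform random proposals, Metropolis acceptance, geometric cooling from
kT 10 to 0.3 over 30 × (total choice count) proposals, best-encountered
assignment returned. A packing run is a pure function of (structure, task,
model, seed); `nstruct` runs distinct seeds and keeps the lowest energy.
An exhaustive enumerator (`exhaustive_pack()`, refusing spaces above 10⁵
states) provides the optimality oracle: on small tasks the annealer
reaches the enumerated optimum in ≥ 95 % of seeded runs, which the test
suite checks on 50 randomized three-site tasks.

## Charge control by reference energies

Lowering a residue type's reference energy makes every placement of that
type cheaper by the same amount, so it monotonically (in expectation)
biases packing toward more of that type. `supercharge_with_refweights()`
packs once at given weights; `supercharge_to_target()` starts from the
defaults and lowers the included types by 0.05 per iteration — both types
of a polarity together, preserving their default offset — re-packing from
the native structure with a fresh seed each iteration until the target net
charge is reached or 60 iterations pass. The step and cap mirror the
granularity at which published weight series move (steps of 0.05–0.25 over
roughly −0.3 to −2.0). Re-packing from the native each iteration keeps the
result a function of the final weights plus seed alone, rather than of the
ramp's history; the ramp trajectory (weights, achieved charge, mutation
count per iteration) is recorded in the result for audit.

## What the synthetic fixtures emulate — and what they do not

All tests run on generated structures: ideal-geometry backbones (helix
φ −57°/ψ −47°, strand −120°/120°, extended 180°/180°) with template side
chains, optional seeded coordinate jitter, a seven-helix bundle for
buried/surface contrast, and three crafted hydrogen-bond motifs placed at
ideal geometry (2.8 Å, collinear) with the spin about the bond axis chosen
to minimize clash: a side-chain-to-backbone loop interaction, an
asparagine helix cap, and an Asn serving simultaneously as donor and
acceptor — the situations in which the two protocols genuinely diverge.

These fixtures are *not* folded miniproteins: they are not energy
minimized, their cores are shallow, and nearly every residue is solvent
exposed. Passing tests therefore demonstrate that the protocols implement
their stated rules (ranking, bookkeeping, preservation, optimality,
determinism) — not that designed variants of a real protein would express
or refold. Quantities that depend on deep burial or large native surfaces
(e.g. the exact mutations-per-charge ratio of a 600-protein benchmark)
are reproduced only as trends at reduced scale: on the synthetic panel the
exposure protocol needs fewer mutations per charge unit than the energy
protocol, with both in the 0.5–1.0 band that the ±1/±2 swap arithmetic
dictates.

## Numerical choices and edge cases

* Strict `<` at every surface cutoff; ties are buried.
* Candidate ties at equal AvNAPSA break by (chain, residue number), making
  the exposure protocol fully deterministic.
* Target overshoot: a ±2 swap may pass the target by one; the achieved
  charge is reported, never silently truncated.
* Repulsion is linearly capped below 0.6·r~min~ so clash scores stay
  finite and rotamer ranking remains well ordered even for accidental
  overlaps.
* Hydrogen-bond energies are continuous in distance (piecewise-linear ramp
  vanishing at both bounds) and in angle (squared-cosine linearity
  factor); there is no jump at the detection boundary.
* Residues with missing side-chain atoms keep their AvNAPSA value (mean
  over present atoms); residues missing backbone N/CA/C are dropped at
  parse with a warning. First altloc wins; occupancy is ignored.
* Multi-chain inputs: all chains are parsed and contribute to neighbor
  counts, energies and hydrogen bonds; design is restricted to one chain
  (default: the first).
* The packer's proposal loop evaluates a compact plain-matrix scoring path;
  its totals agree with the reference `score_structure()` decomposition to
  1e−9, asserted by the tests on every fixture class.

## Problem sizes

The test-suite and acceptance-script panels use 7–15-residue fixtures,
50 randomized three-site packing tasks, and a 14-structure design panel —
sizes chosen so the full stochastic protocol (including 40-iteration
reference-energy ramps) completes in minutes while still exercising every
code path; the protocols themselves have no hard-coded size limits.

## Known limitations

* The energy model is shape-faithful but not calibrated against any
  production score function; computed-energy columns of published design
  tables are not reproducible with it, by design.
* The rotamer library is backbone-independent and small; partially buried
  positions on real proteins would benefit from backbone-dependent
  statistics and off-rotamer minimization, neither of which is
  implemented (`pre_pack` repacks, it does not minimize).
* Preserved hydrogen-bonded side chains cannot even repack; a softer
  policy (fix the type, free the rotamer) would be a one-line change in
  the task builder but is not the default.
* No mmCIF input, no NMR multi-model handling beyond the first model, no
  hydrogen placement.
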