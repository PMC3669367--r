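# superchargeR

Automated "supercharging" of protein surfaces: redesigning a protein to
carry high net positive or negative charge so that partially unfolded
chains repel one another instead of aggregating, which can make thermal
unfolding reversible. The package is aimed at protein engineers who want
to generate charge-variant series of a structure and at method developers
who want a small, fully testable implementation of the two standard
supercharging strategies.

## The two protocols

**Exposure-ranked (AvNAPSA) protocol.** Solvent exposure of residue *i*
is the Average number of Neighboring Atoms Per Side-chain Atom,

    AvNAPSA(i) = mean over side-chain heavy atoms a of i of
                 #{ heavy atoms of other residues within 10 Å of a },

low values meaning high exposure. All N/Q plus D/E (positive design) or
R/K (negative design) residues are sorted by AvNAPSA ascending and
force-mutated one by one — D/E/N/Q → K, or R/K/Q → E and N → D — until the
cumulative charge change reaches the target net charge, or all candidates
below a surface cutoff (e.g. AvNAPSA < 150) are taken. Deterministic; the
protocol never designs arginine and uses aspartate only at native
asparagine positions.

**Energy-guided protocol.** Surface residues (AvNAPSA < 120 by default, or
fewer than 16 Cβ neighbors within 10 Å) that are not preserved — not
G/P/C, not already correctly charged, not side-chain hydrogen bonded with
energy < −0.5 — are repacked by fixed-backbone simulated annealing over a
compact rotamer library under a full-atom model energy

    E = fa_atr + fa_rep + fa_sol + fa_pair + hbond_bb_sc + hbond_sc
        + rotamer + reference ,

and the net charge is steered through the per-type *reference energies*
(defaults R −0.98, K −0.65, D −0.67, E −0.81): lowering a charged type's
reference energy makes the packer place more of it. Either pack at given
weights, or ramp the weights down in steps of 0.05 until a target net
charge is reached.

Net formal charge is `(#Arg + #Lys) − (#Asp + #Glu)`, histidine neutral,
termini ignored.

## Worked example

```r
library(superchargeR)

s <- make_structure("ANQADNAEKA", source_name = "toy")  # synthetic helix
s
#> ProteinStructure 'toy': 10 residues, 71 heavy atoms, chains A
#> net formal charge: -1

asc <- apply_avnapsa_design(s, "positive", target_charge = 3)
asc
#> supercharge design (avnapsa, positive)
#> net charge: -1 -> +3 (3 mutations)
#> Q3K, N2K, E8K
pymol_selection(asc)
#> select mutations, chain A and resi 2+3+8
output_name(asc)
#> toy_A_netq+3_avn50.pdb

rsc <- supercharge_to_target(s, 3,
                             supercharge_options(include_lys = TRUE,
                                                 seed = 1))
rsc
#> supercharge design (energy, positive)
#> net charge: -1 -> +3 (4 mutations)
#> N2K, Q3K, A4K, N6K

compare_designs(s, asc, rsc)
#> design comparison
#>   mutations: 3 vs 4
#>   shared positions: 2 (40%), same type 40%
#>   mutations/charge: 0.75 vs 1.00
#>   hbonds lost (strong/weak): 0/0 vs 0/0
```

Reading the numbers: both protocols reach the requested +3 from −1, but
the exposure protocol gets there in 3 mutations (0.75 mutations per
charge unit — it can use the ±2 Glu→Lys swap) while the energy protocol
needs 4, including a hydrophobic-to-charged A4K mutation the exposure
protocol is not allowed to make. Only two positions are shared — the two
strategies genuinely choose different residues.

Real structures enter through `read_pdb("file.pdb")` (ligands, waters and
hydrogens are ignored; first altloc kept), and results leave through
`write_design_outputs()`: the design log, the residue file that governed
the run, and the output PDB whose name records the protocol, final
reference energies / largest mutated AvNAPSA, and the achieved net
charge.

A command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/supercharge.R",
                                       package="superchargeR"))')" \
    design --pdb in.pdb --mode avnapsa --polarity pos \
    --target-charge 20 --out-dir out
```

with `design`, `fixture` (synthetic structures and hydrogen-bond motifs)
and `annotate` (surface table as TSV) subcommands.

## Package layout

- `R/structure.R` — atom/residue model, PDB I/O, mutation
- `R/surface.R` — AvNAPSA and Cβ-neighbor surface metrics
- `R/avnapsa.R` — the exposure-ranked protocol
- `R/energy.R`, `R/score-fast.R` — the energy model
- `R/packer.R` — design tasks, annealed packing, exhaustive oracle,
  resfiles
- `R/design.R` — reference-weight designs and the target-charge ramp
- `R/compare.R` — protocol comparison statistics
- `R/fixtures.R` — synthetic structures and crafted hydrogen-bond motifs
- `R/report.R` — log / PyMOL selection / output naming
- `vignettes/supercharging.Rmd` — models, parameters, design decisions,
  limitations
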