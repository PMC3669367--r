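Package: superchargeR
Title: Automated Supercharging of Protein Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Redesigns protein surfaces to carry high net positive or negative
    charge ("supercharging"), which can prevent aggregation of partially
    unfolded states and improve refolding. Two automated protocols are
    provided: a deterministic solvent-exposure-ranked protocol that mutates
    the most exposed polar residues (ranked by the average number of
    neighboring atoms per side-chain atom, AvNAPSA), and an energy-guided
    protocol that chooses mutations by fixed-backbone rotamer packing under
    a simplified full-atom energy model, steering net charge through
    charged-residue reference energies. Includes surface classification by
    atom-based and residue-based neighbor counts, a compact rotamer library
    and side-chain builder, geometric hydrogen-bond detection with
    preservation rules, protocol comparison statistics, synthetic structure
    fixtures, and report generation (design log, residue file, PyMOL
    selection, self-documenting output names).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
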