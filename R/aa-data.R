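# Canonical amino-acid tables: name maps, side-chain internal-coordinate
# topology, chi-angle definitions, a compact backbone-independent rotamer
# library, per-element Lennard-Jones parameters, and hydrogen-bond
# donor/acceptor atom sets. These tables are the single source of truth for
# side-chain construction and energy evaluation.

AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)
AA1TO3 <- stats::setNames(names(AA3TO1), AA3TO1)
AA_ONE <- unname(AA3TO1)

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

# Side-chain formal charge at physiological pH; histidine treated as neutral.
AA_FORMAL_CHARGE <- c(R = 1L, K = 1L, D = -1L, E = -1L)

# --- side-chain topology ----------------------------------------------------
# Each side-chain atom beyond the backbone is placed by natural extension
# (NeRF): new atom X bonded to ref c, with bond length |c-X|, bond angle
# b-c-X, and torsion a-b-c-X.  The torsion is either a fixed value (ring
# closure) or chi_k + offset (rotatable).  CB is shared by all non-glycine
# types and placed off the backbone with the improper torsion that yields
# L-chirality.

.sc <- function(atom, elem, a, b, c, bond, angle, chi = NA_integer_,
                offset = 0, tors = NA_real_) {
  data.frame(atom = atom, elem = elem, a = a, b = b, c = c,
             bond = bond, angle = angle, chi = as.integer(chi),
             offset = offset, tors = tors, stringsAsFactors = FALSE)
}

CB_ROW <- .sc("CB", "C", "N", "C", "CA", 1.530, 110.1, tors = 122.6)

SIDECHAIN_TOPOLOGY <- list(
  G = NULL,
  A = NULL,
  S = .sc("OG",  "O", "N",  "CA", "CB", 1.417, 110.8, chi = 1),
  C = .sc("SG",  "S", "N",  "CA", "CB", 1.808, 113.8, chi = 1),
  T = rbind(
    .sc("OG1", "O", "N",  "CA", "CB", 1.433, 109.6, chi = 1),
    .sc("CG2", "C", "N",  "CA", "CB", 1.521, 110.5, chi = 1, offset = -120)
  ),
  V = rbind(
    .sc("CG1", "C", "N",  "CA", "CB", 1.527, 110.5, chi = 1),
    .sc("CG2", "C", "N",  "CA", "CB", 1.527, 110.5, chi = 1, offset = 122.3)
  ),
  L = rbind(
    .sc("CG",  "C", "N",  "CA", "CB", 1.530, 116.3, chi = 1),
    .sc("CD1", "C", "CA", "CB", "CG", 1.521, 110.7, chi = 2),
    .sc("CD2", "C", "CA", "CB", "CG", 1.521, 110.7, chi = 2, offset = 122.5)
  ),
  I = rbind(
    .sc("CG1", "C", "N",  "CA", "CB",  1.530, 110.4, chi = 1),
    .sc("CG2", "C", "N",  "CA", "CB",  1.521, 110.5, chi = 1, offset = -122.3),
    .sc("CD1", "C", "CA", "CB", "CG1", 1.513, 113.9, chi = 2)
  ),
  M = rbind(
    .sc("CG", "C", "N",  "CA", "CB", 1.520, 114.1, chi = 1),
    .sc("SD", "S", "CA", "CB", "CG", 1.803, 112.7, chi = 2),
    .sc("CE", "C", "CB", "CG", "SD", 1.791, 100.9, chi = 3)
  ),
  P = rbind(
    .sc("CG", "C", "N",  "CA", "CB", 1.492, 104.5, chi = 1),
    .sc("CD", "C", "CA", "CB", "CG", 1.503, 106.1, chi = 2)
  ),
  F = rbind(
    .sc("CG",  "C", "N",  "CA",  "CB",  1.502, 113.8, chi = 1),
    .sc("CD1", "C", "CA", "CB",  "CG",  1.384, 120.8, chi = 2),
    .sc("CD2", "C", "CA", "CB",  "CG",  1.384, 120.8, chi = 2, offset = 180),
    .sc("CE1", "C", "CB", "CG",  "CD1", 1.382, 121.0, tors = 180),
    .sc("CE2", "C", "CB", "CG",  "CD2", 1.382, 121.0, tors = 180),
    .sc("CZ",  "C", "CG", "CD1", "CE1", 1.382, 119.9, tors = 0)
  ),
  Y = rbind(
    .sc("CG",  "C", "N",  "CA",  "CB",  1.502, 113.8, chi = 1),
    .sc("CD1", "C", "CA", "CB",  "CG",  1.384, 120.8, chi = 2),
    .sc("CD2", "C", "CA", "CB",  "CG",  1.384, 120.8, chi = 2, offset = 180),
    .sc("CE1", "C", "CB", "CG",  "CD1", 1.382, 121.0, tors = 180),
    .sc("CE2", "C", "CB", "CG",  "CD2", 1.382, 121.0, tors = 180),
    .sc("CZ",  "C", "CG", "CD1", "CE1", 1.382, 119.9, tors = 0),
    .sc("OH",  "O", "CD1", "CE1", "CZ", 1.376, 119.9, tors = 180)
  ),
  W = rbind(
    .sc("CG",  "C", "N",  "CA",  "CB",  1.498, 113.6, chi = 1),
    .sc("CD1", "C", "CA", "CB",  "CG",  1.365, 126.9, chi = 2),
    .sc("CD2", "C", "CA", "CB",  "CG",  1.433, 126.8, chi = 2, offset = 180),
    .sc("NE1", "N", "CB", "CG",  "CD1", 1.374, 110.2, tors = 180),
    .sc("CE2", "C", "CB", "CG",  "CD2", 1.409, 107.2, tors = 180),
    .sc("CE3", "C", "CB", "CG",  "CD2", 1.398, 133.9, tors = 0),
    .sc("CZ2", "C", "CG", "CD2", "CE2", 1.394, 122.4, tors = 180),
    .sc("CZ3", "C", "CG", "CD2", "CE3", 1.382, 118.6, tors = 180),
    .sc("CH2", "C", "CD2", "CE2", "CZ2", 1.368, 117.5, tors = 0)
  ),
  D = rbind(
    .sc("CG",  "C", "N",  "CA", "CB", 1.516, 112.6, chi = 1),
    .sc("OD1", "O", "CA", "CB", "CG", 1.249, 118.4, chi = 2),
    .sc("OD2", "O", "CA", "CB", "CG", 1.249, 118.4, chi = 2, offset = 180)
  ),
  N = rbind(
    .sc("CG",  "C", "N",  "CA", "CB", 1.516, 112.6, chi = 1),
    .sc("OD1", "O", "CA", "CB", "CG", 1.231, 120.8, chi = 2),
    .sc("ND2", "N", "CA", "CB", "CG", 1.328, 116.4, chi = 2, offset = 180)
  ),
  E = rbind(
    .sc("CG",  "C", "N",  "CA", "CB", 1.520, 114.1, chi = 1),
    .sc("CD",  "C", "CA", "CB", "CG", 1.516, 112.6, chi = 2),
    .sc("OE1", "O", "CB", "CG", "CD", 1.249, 118.4, chi = 3),
    .sc("OE2", "O", "CB", "CG", "CD", 1.249, 118.4, chi = 3, offset = 180)
  ),
  Q = rbind(
    .sc("CG",  "C", "N",  "CA", "CB", 1.520, 114.1, chi = 1),
    .sc("CD",  "C", "CA", "CB", "CG", 1.516, 112.6, chi = 2),
    .sc("OE1", "O", "CB", "CG", "CD", 1.231, 120.8, chi = 3),
    .sc("NE2", "N", "CB", "CG", "CD", 1.328, 116.4, chi = 3, offset = 180)
  ),
  K = rbind(
    .sc("CG", "C", "N",  "CA", "CB", 1.520, 114.1, chi = 1),
    .sc("CD", "C", "CA", "CB", "CG", 1.520, 111.3, chi = 2),
    .sc("CE", "C", "CB", "CG", "CD", 1.520, 111.3, chi = 3),
    .sc("NZ", "N", "CG", "CD", "CE", 1.489, 111.9, chi = 4)
  ),
  R = rbind(
    .sc("CG",  "C", "N",  "CA", "CB", 1.520, 114.1, chi = 1),
    .sc("CD",  "C", "CA", "CB", "CG", 1.520, 111.3, chi = 2),
    .sc("NE",  "N", "CB", "CG", "CD", 1.461, 112.0, chi = 3),
    .sc("CZ",  "C", "CG", "CD", "NE", 1.329, 124.2, chi = 4),
    .sc("NH1", "N", "CD", "NE", "CZ", 1.326, 120.0, tors = 0),
    .sc("NH2", "N", "CD", "NE", "CZ", 1.326, 120.0, tors = 180)
  ),
  H = rbind(
    .sc("CG",  "C", "N",  "CA", "CB",  1.497, 113.8, chi = 1),
    .sc("ND1", "N", "CA", "CB", "CG",  1.371, 122.7, chi = 2),
    .sc("CD2", "C", "CA", "CB", "CG",  1.356, 131.2, chi = 2, offset = 180),
    .sc("CE1", "C", "CB", "CG", "ND1", 1.319, 109.3, tors = 180),
    .sc("NE2", "N", "CB", "CG", "CD2", 1.374, 107.2, tors = 180)
  )
)

# Chi angle definitions: one row of four atom names per chi, in order.
CHI_ATOMS <- list(
  S = list(c("N", "CA", "CB", "OG")),
  C = list(c("N", "CA", "CB", "SG")),
  T = list(c("N", "CA", "CB", "OG1")),
  V = list(c("N", "CA", "CB", "CG1")),
  L = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  I = list(c("N", "CA", "CB", "CG1"), c("CA", "CB", "CG1", "CD1")),
  M = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "SD"),
           c("CB", "CG", "SD", "CE")),
  P = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD")),
  F = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  Y = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  W = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  H = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "ND1")),
  D = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  N = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  E = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
           c("CB", "CG", "CD", "OE1")),
  Q = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
           c("CB", "CG", "CD", "OE1")),
  K = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
           c("CB", "CG", "CD", "CE"), c("CG", "CD", "CE", "NZ")),
  R = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
           c("CB", "CG", "CD", "NE"), c("CG", "CD", "NE", "CZ"))
)

# --- rotamer library --------------------------------------------------------
# Compact backbone-independent library: the canonical gauche-/trans/gauche+
# wells per rotatable chi, collapsed to the most populated combinations
# (at most four per type).  Probabilities are coarse occupancy estimates and
# sum to one per type; they feed the -ln(p) rotamer term.

.rot <- function(p, ...) {
  chi <- list(...)
  m <- if (length(chi)) do.call(rbind, chi) else matrix(numeric(0), nrow = length(p), ncol = 0)
  list(chi = m, p = p / sum(p))
}

ROTAMER_LIBRARY <- list(
  G = .rot(1),
  A = .rot(1),
  S = .rot(c(0.45, 0.32, 0.23), -65, 180, 62),
  C = .rot(c(0.50, 0.30, 0.20), -65, 180, 62),
  T = .rot(c(0.45, 0.45, 0.10), -60, 60, 180),
  V = .rot(c(0.55, 0.30, 0.15), 175, -60, 62),
  L = .rot(c(0.55, 0.30, 0.15), c(-65, 175), c(180, 65), c(-85, 65)),
  I = .rot(c(0.55, 0.25, 0.20), c(-65, 170), c(62, 170), c(-57, -60)),
  M = .rot(c(0.35, 0.35, 0.30), c(-65, 180, 75), c(-65, 180, -75),
           c(180, 180, 180)),
  P = .rot(c(0.55, 0.45), c(-27, 39), c(27, -35)),
  F = .rot(c(0.50, 0.35, 0.15), c(-65, 90), c(180, 80), c(62, 90)),
  Y = .rot(c(0.50, 0.35, 0.15), c(-65, 90), c(180, 80), c(62, 90)),
  W = .rot(c(0.40, 0.35, 0.25), c(-65, 95), c(180, -105), c(62, -90)),
  H = .rot(c(0.45, 0.35, 0.20), c(-65, -70), c(180, 60), c(62, -75)),
  D = .rot(c(0.50, 0.35, 0.15), c(-70, -15), c(180, 0), c(62, 0)),
  N = .rot(c(0.45, 0.35, 0.20), c(-65, -20), c(180, 30), c(62, -20)),
  E = .rot(c(0.40, 0.35, 0.25), c(-67, 180, -10), c(180, 180, 0),
           c(-65, -65, -40)),
  Q = .rot(c(0.40, 0.35, 0.25), c(-67, 180, -25), c(180, 180, 0),
           c(-65, -65, -40)),
  K = .rot(c(0.40, 0.35, 0.25), c(-67, 180, 180, 180),
           c(180, 180, 180, 180), c(62, 180, 180, 180)),
  R = .rot(c(0.35, 0.30, 0.20, 0.15), c(-67, 180, 180, 180),
           c(180, 180, 180, 180), c(-67, -167, 180, 180),
           c(62, 180, 180, 180))
)

#' Default rotamer library
#'
#' Returns the compact backbone-independent rotamer set used for side-chain
#' construction and packing: canonical gauche/trans chi-angle wells with
#' coarse prior probabilities (summing to one per residue type).
#'
#' @return A named list, one entry per one-letter amino-acid code, each with
#'   elements `chi` (matrix of chi angles in degrees, one row per rotamer)
#'   and `p` (prior probability per rotamer).
#' @export
#' @examples
#' rot <- default_rotamers()
#' rot$K$chi       # lysine chi-angle rows
#' sum(rot$K$p)    # 1
default_rotamers <- function() ROTAMER_LIBRARY

# --- element parameters -----------------------------------------------------
# Per-element Lennard-Jones radius (Angstrom) and well depth (energy units);
# pair minimum = sum of radii, pair well depth = geometric mean.
LJ_PARAMS <- data.frame(
  elem   = c("C", "N", "O", "S"),
  radius = c(1.70, 1.55, 1.52, 1.80),
  eps    = c(0.12, 0.16, 0.20, 0.25),
  stringsAsFactors = FALSE
)

# --- hydrogen-bond chemistry ------------------------------------------------
# Heavy-atom donors (N-H and O-H) and acceptors with the covalent base atom
# used to evaluate approach linearity.  Backbone: N donates (base CA), O
# accepts (base C).
HB_DONORS_SC <- list(
  R = rbind(c("NE", "CD"), c("NH1", "CZ"), c("NH2", "CZ")),
  K = rbind(c("NZ", "CE")),
  N = rbind(c("ND2", "CG")),
  Q = rbind(c("NE2", "CD")),
  H = rbind(c("ND1", "CG"), c("NE2", "CE1")),
  W = rbind(c("NE1", "CD1")),
  S = rbind(c("OG", "CB")),
  T = rbind(c("OG1", "CB")),
  Y = rbind(c("OH", "CZ"))
)
HB_ACCEPTORS_SC <- list(
  D = rbind(c("OD1", "CG"), c("OD2", "CG")),
  E = rbind(c("OE1", "CD"), c("OE2", "CD")),
  N = rbind(c("OD1", "CG")),
  Q = rbind(c("OE1", "CD")),
  S = rbind(c("OG", "CB")),
  T = rbind(c("OG1", "CB")),
  Y = rbind(c("OH", "CZ")),
  H = rbind(c("ND1", "CG"), c("NE2", "CE1"))
)

# Side-chain atoms carrying the formal charge, used by the statistical pair
# (charge complementarity) term.
CHARGED_GROUP_ATOMS <- list(
  D = c("OD1", "OD2"),
  E = c("OE1", "OE2"),
  K = c("NZ"),
  R = c("NE", "NH1", "NH2")
)

.canonical_aa <- function(aa) aa %in% AA_ONE

.assert_aa <- function(aa) {
  if (length(aa) != 1 || is.na(aa) || !.canonical_aa(aa))
    stop("not a canonical one-letter amino-acid code: ", aa, call. = FALSE)
  invisible(aa)
}
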