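# Synthetic toy structures: ideal-geometry backbones (helix, strand,
# extended) with template side chains, and crafted hydrogen-bond motifs.
# Everything is generated from internal-coordinate tables, deterministically
# for a given specification, so every other module is testable without any
# external structure file.

.BACKBONE_GEOM <- list(
  b_can = 1.458, b_cac = 1.525, b_cn = 1.329, b_co = 1.231,
  a_ncac = 111.2, a_cacn = 116.2, a_cnca = 121.7, a_caco = 120.8
)

.PHIPSI <- list(ideal_helix = c(-57, -47),
                ideal_strand = c(-120, 120),
                extended = c(180, 180))

#' Generate a synthetic structure
#'
#' Builds a single-chain structure from ideal bond lengths and angles with
#' canonical backbone dihedrals (helix phi -57 / psi -47, strand -120/120,
#' extended 180/180). Side chains are placed in their most probable library
#' rotamer. An optional Gaussian coordinate perturbation (standard deviation
#' `perturb` Angstrom, seeded) roughens the geometry without breaking
#' residue topology. Deterministic for a given specification.
#'
#' @param sequence One-letter amino-acid string.
#' @param backbone One of `"ideal_helix"`, `"ideal_strand"`, `"extended"`.
#' @param chain Chain identifier.
#' @param start_resno First residue number.
#' @param perturb Coordinate jitter standard deviation in Angstrom (0 = none).
#' @param seed Seed for the jitter.
#' @param source_name Label for reports and output names.
#' @return A [protein_structure()].
#' @export
#' @examples
#' hx <- make_structure("ADKNQAAEKAAQNRA")
#' hx
make_structure <- function(sequence,
                           backbone = c("ideal_helix", "ideal_strand",
                                        "extended"),
                           chain = "A", start_resno = 1L, perturb = 0,
                           seed = 0L, source_name = "fixture") {
  backbone <- match.arg(backbone)
  seq1 <- strsplit(sequence, "")[[1]]
  if (!length(seq1)) stop("empty sequence", call. = FALSE)
  bad <- setdiff(unique(seq1), AA_ONE)
  if (length(bad)) stop("unknown amino-acid letter(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  pp <- .PHIPSI[[backbone]]
  phi <- rep(pp[1], length(seq1)); psi <- rep(pp[2], length(seq1))
  g <- .BACKBONE_GEOM
  nres <- length(seq1)
  # backbone trace
  N <- CA <- C <- O <- matrix(NA_real_, nres, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_can, 0, 0)
  ang <- g$a_ncac * pi / 180
  C[1, ] <- CA[1, ] + g$b_cac * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(nres)) {
    if (i > 1) {
      N[i, ] <- .place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                            g$b_cn, g$a_cacn, psi[i - 1])
      CA[i, ] <- .place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                             g$b_can, g$a_cnca, 180)  # trans omega
      C[i, ] <- .place_atom(C[i - 1, ], N[i, ], CA[i, ],
                            g$b_cac, g$a_ncac, phi[i])
    }
    O[i, ] <- .place_atom(N[i, ], CA[i, ], C[i, ], g$b_co, g$a_caco,
                          psi[i] + 180)
  }
  rows <- vector("list", nres)
  for (i in seq_len(nres)) {
    aa <- seq1[i]
    bb <- data.frame(atom = c("N", "CA", "C", "O"),
                     elem = c("N", "C", "C", "O"),
                     x = c(N[i, 1], CA[i, 1], C[i, 1], O[i, 1]),
                     y = c(N[i, 2], CA[i, 2], C[i, 2], O[i, 2]),
                     z = c(N[i, 3], CA[i, 3], C[i, 3], O[i, 3]),
                     stringsAsFactors = FALSE)
    lib <- ROTAMER_LIBRARY[[aa]]
    chis <- if (ncol(lib$chi)) lib$chi[which.max(lib$p), ] else numeric(0)
    sc <- .build_sidechain(aa, N[i, ], CA[i, ], C[i, ], chis)
    at <- rbind(bb, sc)
    rows[[i]] <- data.frame(chain = chain, resno = start_resno + i - 1L,
                            icode = "", resid = AA1TO3[[aa]],
                            atom = at$atom, x = at$x, y = at$y, z = at$z,
                            stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, rows)
  if (perturb > 0) {
    jitter <- .with_seed(seed, stats::rnorm(3 * nrow(atoms), sd = perturb))
    atoms$x <- atoms$x + jitter[seq_len(nrow(atoms))]
    atoms$y <- atoms$y + jitter[nrow(atoms) + seq_len(nrow(atoms))]
    atoms$z <- atoms$z + jitter[2 * nrow(atoms) + seq_len(nrow(atoms))]
  }
  protein_structure(atoms, source_name = source_name)
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Rigidly place structure `seg` so that its atom `anchor` (site key + atom
# name) lands at `target`, with the direction from `tail_atom` to `anchor`
# aligned to unit vector `dir`, then optionally spun about `dir`.
.place_segment <- function(seg, anchor_site, anchor_atom, tail_atom,
                           target, dir, spin = 0) {
  i <- .resolve_site(seg, anchor_site)
  a <- seg$atoms
  ai <- which(a$res_index == i & a$atom == anchor_atom)
  ti <- which(a$res_index == i & a$atom == tail_atom)
  stopifnot(length(ai) == 1, length(ti) == 1)
  p_anchor <- unlist(a[ai, c("x", "y", "z")])
  p_tail <- unlist(a[ti, c("x", "y", "z")])
  R1 <- .rotation_between(p_anchor - p_tail, dir)
  seg <- transform_structure(seg, R1, -as.numeric(R1 %*% p_anchor))
  if (spin != 0)
    seg <- transform_structure(seg, .axis_rotation(dir, spin), c(0, 0, 0))
  transform_structure(seg, diag(3), target)
}

# Place `seg` with .place_segment, scanning the free spin about the bond
# axis for the orientation with the least steric clash against `main`.
.place_segment_clear <- function(main, seg, anchor_site, anchor_atom,
                                 tail_atom, target, dir) {
  best <- NULL; best_rep <- Inf
  for (sp in seq(0, 330, by = 30)) {
    placed <- .place_segment(seg, anchor_site, anchor_atom, tail_atom,
                             target, dir, spin = sp)
    rep_e <- score_structure(merge_structures(main, placed))$terms[["fa_rep"]]
    if (rep_e < best_rep) {
      best_rep <- rep_e
      best <- placed
    }
  }
  best
}

#' Crafted hydrogen-bond motif fixtures
#'
#' Builds small structures containing deliberately placed side-chain
#' hydrogen bonds at ideal geometry (2.8 Angstrom donor-acceptor distance,
#' collinear approach), the situations in which exposure-ranked and
#' energy-guided supercharging diverge:
#'
#' * `sidechain_to_backbone_loop` - an exposed aspartate whose carboxylate
#'   accepts a hydrogen bond from a backbone amide of a nearby loop segment
#'   (one strong sidechain-backbone bond).
#' * `helix_cap` - an asparagine side chain capping the free amide at a
#'   helix N-terminus (one strong sidechain-backbone bond).
#' * `NQ_donor_acceptor` - an asparagine acting simultaneously as acceptor
#'   (OD1 from a backbone amide) and donor (ND2 to a backbone carbonyl),
#'   two strong bonds.
#'
#' @param motif Motif name, see above.
#' @return A [protein_structure()].
#' @export
make_hbond_motif <- function(motif = c("sidechain_to_backbone_loop",
                                       "helix_cap", "NQ_donor_acceptor")) {
  motif <- match.arg(motif)
  if (motif == "sidechain_to_backbone_loop") {
    main <- make_structure("AADAAQN", backbone = "ideal_helix",
                           start_resno = 10L, source_name = "hb_loop")
    asp <- .resolve_site(main, "A:12")
    a <- main$atoms
    od1 <- unlist(a[a$res_index == asp & a$atom == "OD1", c("x", "y", "z")])
    cg <- unlist(a[a$res_index == asp & a$atom == "CG", c("x", "y", "z")])
    u <- .vunit(od1 - cg)
    seg <- make_structure("A", backbone = "extended", start_resno = 1L)
    # donor: the segment backbone N; its CA points away from OD1 so the
    # base-donor-acceptor approach is collinear
    out <- .place_segment_clear(main, seg, "A:1", "N", "CA",
                                od1 + 2.8 * u, -u)
    return(merge_structures(main, out))
  }
  if (motif == "helix_cap") {
    main <- make_structure("AAQAAAAA", backbone = "ideal_helix",
                           start_resno = 10L, source_name = "hb_cap")
    a <- main$atoms
    i10 <- .resolve_site(main, "A:10")
    n10 <- unlist(a[a$res_index == i10 & a$atom == "N", c("x", "y", "z")])
    ca10 <- unlist(a[a$res_index == i10 & a$atom == "CA", c("x", "y", "z")])
    v <- .vunit(n10 - ca10)
    cap <- make_structure("N", backbone = "extended", start_resno = 1L)
    # acceptor: OD1 lands on the donor axis, carbonyl carbon on the far side
    out <- .place_segment_clear(main, cap, "A:1", "OD1", "CG",
                                n10 + 2.8 * v, -v)
    return(merge_structures(main, out))
  }
  # NQ_donor_acceptor
  main <- make_structure("AANAA", backbone = "ideal_helix",
                         start_resno = 10L, source_name = "hb_nq")
  asn <- .resolve_site(main, "A:12")
  a <- main$atoms
  od1 <- unlist(a[a$res_index == asn & a$atom == "OD1", c("x", "y", "z")])
  nd2 <- unlist(a[a$res_index == asn & a$atom == "ND2", c("x", "y", "z")])
  cg <- unlist(a[a$res_index == asn & a$atom == "CG", c("x", "y", "z")])
  u <- .vunit(od1 - cg)
  seg1 <- make_structure("A", backbone = "extended", start_resno = 1L)
  s1 <- .place_segment_clear(main, seg1, "A:1", "N", "CA", od1 + 2.8 * u, -u)
  with_s1 <- merge_structures(main, s1)
  w <- .vunit(nd2 - cg)
  seg2 <- make_structure("A", backbone = "extended", start_resno = 21L)
  # acceptor segment: its backbone O sits on the ND2 donor axis
  s2 <- .place_segment_clear(with_s1, seg2, "A:21", "O", "C",
                             nd2 + 2.8 * w, -w)
  merge_structures(with_s1, s2)
}
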