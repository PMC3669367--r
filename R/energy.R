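# Simplified full-atom pairwise energy model. The shapes follow the classic
# fixed-backbone design decomposition: Lennard-Jones attraction and repulsion
# (capped), an implicit-solvation burial penalty for polar atoms, a
# statistical charge-complementarity pair term, geometric hydrogen bonding
# split into sidechain-sidechain and sidechain-backbone classes, a rotamer
# probability term, and per-residue-type reference energies. It is
# deliberately compact and auditable; all parameters live in one model
# object. Terms whose value cannot change in fixed-backbone design
# (backbone-backbone hydrogen bonds) are excluded.

#' Construct an energy model
#'
#' All tunable parameters of the scoring function in one object. Defaults:
#' unit weights for every term; charged-residue reference energies
#' R -0.98, K -0.65, D -0.67, E -0.81 (all other types 0); hydrogen-bond
#' preservation threshold -0.5 energy units; pair-term distance cutoff
#' 6.5 Angstrom.
#'
#' @param weights Named numeric vector of term weights (`fa_atr`, `fa_rep`,
#'   `fa_sol`, `fa_pair`, `hbond_bb_sc`, `hbond_sc`, `rotamer`, `reference`).
#' @param reference_energies Named numeric vector over one-letter codes;
#'   omitted types default to 0.
#' @param hbond_preserve_threshold Side chains in hydrogen bonds stronger
#'   (more negative) than this are preserved during design; must be negative.
#' @param pair_distance_cutoff,pair_switch_start Charged-pair term range:
#'   full magnitude below `pair_switch_start`, linearly switched off at
#'   `pair_distance_cutoff` (Angstrom).
#' @param atr_cutoff Lennard-Jones attraction cutoff (Angstrom).
#' @param rep_cap_frac Below this fraction of the pair minimum the repulsion
#'   continues linearly (keeps clash scores finite).
#' @param sol_radius,sol_threshold,sol_polar_weight,sol_carbon_weight
#'   Burial model: an atom's neighbor count within `sol_radius` above
#'   `sol_threshold` is penalized (polar N/O) or slightly rewarded (C/S).
#' @param hbond_dmin,hbond_ideal,hbond_dmax Donor-acceptor heavy-atom
#'   distance bounds and optimum (Angstrom).
#' @param lj_params Per-element radius/well-depth table.
#' @return An object of class `energy_model`.
#' @export
#' @examples
#' m <- energy_model()
#' reference_energy("R", m)   # -0.98
energy_model <- function(weights = c(fa_atr = 1, fa_rep = 1, fa_sol = 1,
                                     fa_pair = 1, hbond_bb_sc = 1,
                                     hbond_sc = 1, rotamer = 1,
                                     reference = 1),
                         reference_energies = c(R = -0.98, K = -0.65,
                                                D = -0.67, E = -0.81),
                         hbond_preserve_threshold = -0.5,
                         pair_distance_cutoff = 6.5,
                         pair_switch_start = 5.5,
                         atr_cutoff = 6.0,
                         rep_cap_frac = 0.6,
                         sol_radius = 5.0,
                         sol_threshold = 16,
                         sol_polar_weight = 0.08,
                         sol_carbon_weight = -0.01,
                         hbond_dmin = 2.4,
                         hbond_ideal = 2.8,
                         hbond_dmax = 3.6,
                         lj_params = LJ_PARAMS) {
  ref <- stats::setNames(rep(0, length(AA_ONE)), AA_ONE)
  ref[names(reference_energies)] <- reference_energies
  if (!(hbond_preserve_threshold < 0))
    stop("hbond_preserve_threshold must be negative", call. = FALSE)
  need <- c("fa_atr", "fa_rep", "fa_sol", "fa_pair", "hbond_bb_sc",
            "hbond_sc", "rotamer", "reference")
  w <- stats::setNames(rep(1, length(need)), need)
  w[names(weights)] <- weights
  structure(list(weights = w, reference_energies = ref,
                 hbond_preserve_threshold = hbond_preserve_threshold,
                 pair_distance_cutoff = pair_distance_cutoff,
                 pair_switch_start = pair_switch_start,
                 atr_cutoff = atr_cutoff, rep_cap_frac = rep_cap_frac,
                 sol_radius = sol_radius, sol_threshold = sol_threshold,
                 sol_polar_weight = sol_polar_weight,
                 sol_carbon_weight = sol_carbon_weight,
                 hbond_dmin = hbond_dmin, hbond_ideal = hbond_ideal,
                 hbond_dmax = hbond_dmax, lj_params = lj_params),
            class = "energy_model")
}

#' Reference energy of an amino-acid type
#'
#' @param aa One-letter amino-acid code.
#' @param model An [energy_model()].
#' @return The stored per-residue reference energy.
#' @export
reference_energy <- function(aa, model = energy_model()) {
  .assert_aa(aa)
  unname(model$reference_energies[aa])
}

#' Read an energy configuration file
#'
#' Line-oriented `key = value` overrides for [energy_model()] parameters.
#' Keys may be weight names (`fa_rep`), reference energies (`ref_K`), or any
#' scalar model parameter (`sol_radius`). Lines starting with `#` are
#' ignored.
#'
#' @param path Path to the configuration file.
#' @return An `energy_model` with the overrides applied.
#' @export
read_energy_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  model <- energy_model()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln, call. = FALSE)
    key <- trimws(kv[1]); val <- as.numeric(trimws(kv[2]))
    if (is.na(val)) stop("non-numeric value in config line: ", ln,
                         call. = FALSE)
    if (key %in% names(model$weights)) {
      model$weights[key] <- val
    } else if (grepl("^ref_", key)) {
      aa <- sub("^ref_", "", key)
      .assert_aa(aa)
      model$reference_energies[aa] <- val
    } else if (key %in% names(model) && is.numeric(model[[key]]) &&
               length(model[[key]]) == 1) {
      model[[key]] <- val
    } else stop("unknown config key: ", key, call. = FALSE)
  }
  model
}

# --- scoring internals ------------------------------------------------------

.lj_tables <- function(model) {
  rad <- stats::setNames(model$lj_params$radius, model$lj_params$elem)
  eps <- stats::setNames(model$lj_params$eps, model$lj_params$elem)
  list(rad = rad, eps = eps)
}

# Split LJ into attraction (<= 0, plateau -eps inside the minimum, cut at
# atr_cutoff) and repulsion (>= 0, zero outside the minimum, linear below
# rep_cap_frac * rmin).
.lj_atr_rep <- function(d, rmin, eps, model) {
  atr <- numeric(length(d))
  rep_ <- numeric(length(d))
  inside <- d < rmin
  mid <- !inside & d <= model$atr_cutoff
  x6 <- (rmin[mid] / d[mid])^6
  atr[mid] <- eps[mid] * (x6 * x6 - 2 * x6)
  atr[inside] <- -eps[inside]
  cap <- model$rep_cap_frac * rmin
  lin <- d < cap
  core <- inside & !lin
  x6c <- (rmin[core] / d[core])^6
  rep_[core] <- eps[core] * (x6c * x6c - 2 * x6c) + eps[core]
  if (any(lin)) {
    dc <- cap[lin]
    x6l <- (rmin[lin] / dc)^6
    val <- eps[lin] * (x6l * x6l - 2 * x6l) + eps[lin]
    slope <- eps[lin] * 12 * (rmin[lin]^12 / dc^13 - rmin[lin]^6 / dc^7)
    rep_[lin] <- val + slope * (dc - d[lin])
  }
  list(atr = atr, rep = rep_)
}

# Hydrogen-bond donor/acceptor inventory of a structure: global atom row
# indices plus the covalent base atom used for the linearity factor.
# Columns: atom index, base index, backbone flag (1/0).
.hb_participants <- function(structure) {
  a <- structure$atoms
  lookup_key <- paste(a$res_index, a$atom)
  rt_first <- !duplicated(a$res_index)
  res_ids <- a$res_index[rt_first]
  res_aa <- a$aa[rt_first]
  at_of <- function(res, atom) match(paste(res, atom), lookup_key)
  # backbone amide donors (proline has no N-H) and carbonyl acceptors
  dres <- res_ids[res_aa != "P"]
  don <- cbind(at_of(dres, "N"), at_of(dres, "CA"), 1L)
  acc <- cbind(at_of(res_ids, "O"), at_of(res_ids, "C"), 1L)
  acc <- acc[!is.na(acc[, 1]), , drop = FALSE]
  for (aa in intersect(names(HB_DONORS_SC), unique(res_aa))) {
    tab <- HB_DONORS_SC[[aa]]
    rr <- res_ids[res_aa == aa]
    for (k in seq_len(nrow(tab)))
      don <- rbind(don, cbind(at_of(rr, tab[k, 1]), at_of(rr, tab[k, 2]), 0L))
  }
  for (aa in intersect(names(HB_ACCEPTORS_SC), unique(res_aa))) {
    tab <- HB_ACCEPTORS_SC[[aa]]
    rr <- res_ids[res_aa == aa]
    for (k in seq_len(nrow(tab)))
      acc <- rbind(acc, cbind(at_of(rr, tab[k, 1]), at_of(rr, tab[k, 2]), 0L))
  }
  don <- don[!is.na(don[, 1]) & !is.na(don[, 2]), , drop = FALSE]
  acc <- acc[!is.na(acc[, 1]) & !is.na(acc[, 2]), , drop = FALSE]
  list(donors = don, acceptors = acc)
}

.hb_ramp <- function(d, model) {
  r <- ifelse(d <= model$hbond_ideal,
              (d - model$hbond_dmin) / (model$hbond_ideal - model$hbond_dmin),
              (model$hbond_dmax - d) / (model$hbond_dmax - model$hbond_ideal))
  pmax(0, pmin(1, r))
}

# Residue-level adjacency (same chain, sequence-neighbor residue numbers):
# such pairs are covalently linked, so their interactions are excluded from
# the pairwise terms (a coarse bonded-pair exclusion).
.residue_adjacency <- function(chain, resno) {
  n <- length(chain)
  outer(seq_len(n), seq_len(n), function(i, j)
    chain[i] == chain[j] & abs(resno[i] - resno[j]) == 1)
}

#' Detect side-chain hydrogen bonds
#'
#' Geometric scan over heavy-atom donor/acceptor pairs (N/O donors, O and
#' histidine-N acceptors) with donor-acceptor distance between the model's
#' bounds. The bond energy is `-(distance ramp) x (linearity factor)` times
#' the class weight: -1 at ideal geometry (2.8 Angstrom, collinear
#' base-donor-acceptor approach), 0 at the distance bounds, continuous in
#' between. Backbone-backbone pairs and covalently adjacent residues are
#' skipped; bonds are classed `sc_sc` (sidechain-sidechain) or `sc_bb`
#' (sidechain-backbone) and labelled strong (below the preservation
#' threshold), weak (down to -0.1), or negligible.
#'
#' @param structure A [protein_structure()].
#' @param model An [energy_model()].
#' @return data.frame with one row per bond: donor/acceptor site keys and
#'   atom names, distance, approach angle, energy, class, strength.
#' @export
detect_sidechain_hbonds <- function(structure, model = energy_model()) {
  a <- structure$atoms
  hb <- .hb_participants(structure)
  empty <- data.frame(donor_key = character(0), donor_atom = character(0),
                      acceptor_key = character(0),
                      acceptor_atom = character(0), distance = numeric(0),
                      angle = numeric(0), energy = numeric(0),
                      class = character(0), strength = character(0),
                      stringsAsFactors = FALSE)
  if (is.null(hb$donors) || is.null(hb$acceptors) ||
      !nrow(hb$donors) || !nrow(hb$acceptors)) return(empty)
  rt <- residue_sites(structure)
  adj <- .residue_adjacency(rt$chain, rt$number)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  nd <- nrow(hb$donors); na_ <- nrow(hb$acceptors)
  di <- rep(seq_len(nd), times = na_)
  ai <- rep(seq_len(na_), each = nd)
  d_at <- hb$donors[di, 1]; d_base <- hb$donors[di, 2]
  d_bb <- hb$donors[di, 3] == 1L
  a_at <- hb$acceptors[ai, 1]; a_bb <- hb$acceptors[ai, 3] == 1L
  d_res <- a$res_index[d_at]; a_res <- a$res_index[a_at]
  keep <- d_res != a_res & !(d_bb & a_bb) & !adj[cbind(d_res, a_res)]
  if (!any(keep)) return(empty)
  sel <- which(keep)
  dv <- xyz[a_at[sel], , drop = FALSE] - xyz[d_at[sel], , drop = FALSE]
  dd <- sqrt(rowSums(dv * dv))
  inr <- dd >= model$hbond_dmin & dd <= model$hbond_dmax
  if (!any(inr)) return(empty)
  sel <- sel[inr]; dd <- dd[inr]
  bv <- xyz[d_base[sel], , drop = FALSE] - xyz[d_at[sel], , drop = FALSE]
  av <- xyz[a_at[sel], , drop = FALSE] - xyz[d_at[sel], , drop = FALSE]
  cosang <- rowSums(bv * av) /
    (sqrt(rowSums(bv * bv)) * sqrt(rowSums(av * av)))
  cosang <- pmax(-1, pmin(1, cosang))
  f <- pmax(0, -cosang)^2
  e_raw <- -.hb_ramp(dd, model) * f
  ok <- e_raw < -1e-9
  if (!any(ok)) return(empty)
  sel <- sel[ok]; dd <- dd[ok]; e_raw <- e_raw[ok]
  ang <- acos(cosang[ok]) * 180 / pi
  cls <- ifelse(hb$donors[di[sel], 3] == 1L | hb$acceptors[ai[sel], 3] == 1L,
                "sc_bb", "sc_sc")
  w <- ifelse(cls == "sc_bb", model$weights[["hbond_bb_sc"]],
              model$weights[["hbond_sc"]])
  e <- e_raw * w
  res <- data.frame(
    donor_key = rt$key[a$res_index[hb$donors[di[sel], 1]]],
    donor_atom = a$atom[hb$donors[di[sel], 1]],
    acceptor_key = rt$key[a$res_index[hb$acceptors[ai[sel], 1]]],
    acceptor_atom = a$atom[hb$acceptors[ai[sel], 1]],
    distance = dd, angle = ang, energy = e, class = cls,
    strength = ifelse(e < model$hbond_preserve_threshold, "strong",
                      ifelse(e < -0.1, "weak", "negligible")),
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Score a structure
#'
#' Evaluates the weighted sum of all model terms and a per-residue
#' decomposition (pairwise contributions split half-half between partners).
#' The decomposition sums to the total to floating tolerance.
#'
#' @param structure A [protein_structure()].
#' @param model An [energy_model()].
#' @param rotamers Rotamer library for the rotamer-probability term.
#' @return Object of class `supercharge_score`: list with `total`, `terms`
#'   (named, weighted), `per_residue` (data.frame, one row per site), and
#'   `hbonds` (the detected side-chain hydrogen bonds).
#' @export
score_structure <- function(structure, model = energy_model(),
                            rotamers = default_rotamers()) {
  a <- structure$atoms
  n <- nrow(a)
  rt <- residue_sites(structure)
  nres <- nrow(rt)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  res <- a$res_index
  adj_res <- .residue_adjacency(rt$chain, rt$number)
  per <- matrix(0, nres, 8,
                dimnames = list(NULL, c("fa_atr", "fa_rep", "fa_sol",
                                        "fa_pair", "hbond_bb_sc", "hbond_sc",
                                        "rotamer", "reference")))
  D <- as.matrix(stats::dist(xyz))
  diff_res <- outer(res, res, "!=")
  adj_atom <- adj_res[res, res, drop = FALSE]

  # Lennard-Jones over pairs with at least one side-chain atom
  lj <- .lj_tables(model)
  sc <- !a$backbone
  mask <- upper.tri(D) & diff_res & !adj_atom &
    (outer(sc, sc, "|"))
  idx <- which(mask)
  if (length(idx)) {
    ii <- ((idx - 1) %% n) + 1
    jj <- ((idx - 1) %/% n) + 1
    d <- D[idx]
    keep <- d <= max(model$atr_cutoff, 2 * max(lj$rad))
    ii <- ii[keep]; jj <- jj[keep]; d <- d[keep]
    rmin <- lj$rad[a$elem[ii]] + lj$rad[a$elem[jj]]
    eps <- sqrt(lj$eps[a$elem[ii]] * lj$eps[a$elem[jj]])
    e <- .lj_atr_rep(d, rmin, eps, model)
    watr <- model$weights[["fa_atr"]]; wrep <- model$weights[["fa_rep"]]
    grp <- c(res[ii], res[jj])
    atr2 <- rowsum(c(e$atr, e$atr) / 2, grp)
    rep2 <- rowsum(c(e$rep, e$rep) / 2, grp)
    gi <- as.integer(rownames(atr2))
    per[gi, "fa_atr"] <- per[gi, "fa_atr"] + watr * atr2[, 1]
    per[gi, "fa_rep"] <- per[gi, "fa_rep"] + wrep * rep2[, 1]
  }

  # implicit solvation: burial of polar atoms, slight reward for carbon
  nbr <- rowSums(D < model$sol_radius & diff_res)
  excess <- pmax(0, nbr - model$sol_threshold)
  polar <- a$elem %in% c("N", "O")
  sol_atom <- ifelse(polar, model$sol_polar_weight * excess,
                     model$sol_carbon_weight * excess)
  wsol <- model$weights[["fa_sol"]]
  sol2 <- rowsum(sol_atom, res)
  per[as.integer(rownames(sol2)), "fa_sol"] <- wsol * sol2[, 1]

  # statistical charge-complementarity pair term
  charged <- which(rt$aa %in% names(CHARGED_GROUP_ATOMS))
  wpair <- model$weights[["fa_pair"]]
  if (length(charged) > 1) {
    for (u in seq_along(charged)[-1]) {
      for (v in seq_len(u - 1)) {
        ri <- charged[u]; rj <- charged[v]
        if (adj_res[ri, rj]) next
        ai <- which(res == ri & a$atom %in% CHARGED_GROUP_ATOMS[[rt$aa[ri]]])
        aj <- which(res == rj & a$atom %in% CHARGED_GROUP_ATOMS[[rt$aa[rj]]])
        if (!length(ai) || !length(aj)) next
        dmin <- min(D[ai, aj])
        if (dmin >= model$pair_distance_cutoff) next
        s <- if (dmin <= model$pair_switch_start) 1 else
          (model$pair_distance_cutoff - dmin) /
          (model$pair_distance_cutoff - model$pair_switch_start)
        sgn <- AA_FORMAL_CHARGE[rt$aa[ri]] * AA_FORMAL_CHARGE[rt$aa[rj]]
        e <- wpair * sign(sgn) * 0.5 * s
        per[ri, "fa_pair"] <- per[ri, "fa_pair"] + e / 2
        per[rj, "fa_pair"] <- per[rj, "fa_pair"] + e / 2
      }
    }
  }

  # hydrogen bonds (side-chain mediated only)
  hb <- detect_sidechain_hbonds(structure, model)
  if (nrow(hb)) {
    di <- match(hb$donor_key, rt$key)
    ai <- match(hb$acceptor_key, rt$key)
    for (k in seq_len(nrow(hb))) {
      col <- if (hb$class[k] == "sc_bb") "hbond_bb_sc" else "hbond_sc"
      per[di[k], col] <- per[di[k], col] + hb$energy[k] / 2
      per[ai[k], col] <- per[ai[k], col] + hb$energy[k] / 2
    }
  }

  # rotamer probability and reference terms
  wrot <- model$weights[["rotamer"]]; wref <- model$weights[["reference"]]
  for (i in seq_len(nres)) {
    res_atoms <- a[res == i, c("atom", "x", "y", "z")]
    chis <- .measure_chis(res_atoms, rt$aa[i])
    nr <- .nearest_rotamer(rt$aa[i], chis, rotamers)
    per[i, "rotamer"] <- wrot * (-log(nr$p))
    per[i, "reference"] <- wref * model$reference_energies[rt$aa[i]]
  }

  terms <- colSums(per)
  per_residue <- cbind(rt[, c("chain", "number", "icode", "aa", "key")],
                       as.data.frame(per))
  per_residue$total <- rowSums(per)
  structure(list(total = sum(terms), terms = terms,
                 per_residue = per_residue, hbonds = hb),
            class = "supercharge_score")
}

#' @export
print.supercharge_score <- function(x, ...) {
  cat("total energy:", format(x$total, digits = 6), "\n")
  print(round(x$terms, 4))
  invisible(x)
}

# Repulsive clash score of a candidate side chain (data.frame atom/elem/xyz)
# against all atoms of other, non-adjacent residues. Used to pick the
# lowest-clash rotamer when force-mutating.
.sidechain_clash <- function(sc, structure, res_index, model) {
  if (!nrow(sc)) return(0)
  a <- structure$atoms
  rt <- residue_sites(structure)
  adj <- .residue_adjacency(rt$chain, rt$number)
  other <- which(a$res_index != res_index & !adj[res_index, a$res_index])
  if (!length(other)) return(0)
  lj <- .lj_tables(model)
  tot <- 0
  oxyz <- as.matrix(a[other, c("x", "y", "z")])
  oel <- a$elem[other]
  for (k in seq_len(nrow(sc))) {
    d <- sqrt(colSums((t(oxyz) - c(sc$x[k], sc$y[k], sc$z[k]))^2))
    rmin <- lj$rad[sc$elem[k]] + lj$rad[oel]
    eps <- sqrt(lj$eps[sc$elem[k]] * lj$eps[oel])
    near <- d < rmin
    if (any(near)) {
      e <- .lj_atr_rep(d[near], rmin[near], eps[near], model)
      tot <- tot + sum(e$rep)
    }
  }
  tot
}
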