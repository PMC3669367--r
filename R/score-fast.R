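# Compact scoring path used inside the packer's proposal loop: residues are
# pre-digested into plain-matrix blocks so that evaluating a candidate
# assignment avoids data.frame bookkeeping. Totals agree with
# score_structure() to floating tolerance (asserted by the test suite);
# score_structure() remains the reference implementation and provides the
# per-residue decomposition.

# Digest one residue's atom data.frame into a compact block.
.compact_block <- function(res_df, rotamers = ROTAMER_LIBRARY,
                           logp = NULL) {
  aa <- res_df$aa[1]
  xyz <- as.matrix(res_df[, c("x", "y", "z")])
  dimnames(xyz) <- NULL
  atom <- res_df$atom
  if (is.null(logp)) {
    chis <- .measure_chis(res_df, aa)
    logp <- -log(.nearest_rotamer(aa, chis, rotamers)$p)
  }
  loc <- function(name) match(name, atom)
  don <- NULL; acc <- NULL
  if (aa != "P") don <- rbind(don, c(loc("N"), loc("CA"), 1L))
  if (!is.na(loc("O"))) acc <- rbind(acc, c(loc("O"), loc("C"), 1L))
  dsc <- HB_DONORS_SC[[aa]]
  if (!is.null(dsc)) for (k in seq_len(nrow(dsc))) {
    i <- loc(dsc[k, 1]); b <- loc(dsc[k, 2])
    if (!is.na(i) && !is.na(b)) don <- rbind(don, c(i, b, 0L))
  }
  asc <- HB_ACCEPTORS_SC[[aa]]
  if (!is.null(asc)) for (k in seq_len(nrow(asc))) {
    i <- loc(asc[k, 1]); b <- loc(asc[k, 2])
    if (!is.na(i) && !is.na(b)) acc <- rbind(acc, c(i, b, 0L))
  }
  ch <- CHARGED_GROUP_ATOMS[[aa]]
  charged <- if (is.null(ch)) integer(0) else {
    v <- match(ch, atom); v[!is.na(v)]
  }
  list(natoms = nrow(res_df), xyz = xyz, elem = res_df$elem,
       bb = res_df$backbone, aa = aa, logp = logp,
       don = don, acc = acc, charged = charged)
}

# Total model energy of an assignment of compact blocks. `chain`/`resno`
# are per-residue vectors (for the bonded-neighbor exclusion).
.score_compact <- function(blocks, chain, resno, model) {
  nres <- length(blocks)
  natoms <- vapply(blocks, `[[`, integer(1), "natoms")
  off <- c(0L, cumsum(natoms))[seq_len(nres)]
  xyz <- do.call(rbind, lapply(blocks, `[[`, "xyz"))
  elem <- unlist(lapply(blocks, `[[`, "elem"), use.names = FALSE)
  bb <- unlist(lapply(blocks, `[[`, "bb"), use.names = FALSE)
  res <- rep.int(seq_len(nres), natoms)
  n <- nrow(xyz)
  adj_res <- .residue_adjacency(chain, resno)
  D <- as.matrix(stats::dist(xyz))
  diff_res <- outer(res, res, "!=")
  adj_atom <- adj_res[res, res, drop = FALSE]
  lj <- .lj_tables(model)
  sc <- !bb
  mask <- upper.tri(D) & diff_res & !adj_atom & outer(sc, sc, "|")
  idx <- which(mask)
  e_atr <- 0; e_rep <- 0
  if (length(idx)) {
    d <- D[idx]
    keep <- d <= max(model$atr_cutoff, 2 * max(lj$rad))
    idx <- idx[keep]; d <- d[keep]
    ii <- ((idx - 1) %% n) + 1
    jj <- ((idx - 1) %/% n) + 1
    rmin <- lj$rad[elem[ii]] + lj$rad[elem[jj]]
    eps <- sqrt(lj$eps[elem[ii]] * lj$eps[elem[jj]])
    e <- .lj_atr_rep(d, rmin, eps, model)
    e_atr <- sum(e$atr); e_rep <- sum(e$rep)
  }
  nbr <- rowSums(D < model$sol_radius & diff_res)
  excess <- pmax(0, nbr - model$sol_threshold)
  polar <- elem %in% c("N", "O")
  e_sol <- sum(ifelse(polar, model$sol_polar_weight,
                      model$sol_carbon_weight) * excess)
  # charged-pair term
  e_pair <- 0
  chg_res <- which(vapply(blocks, function(b) length(b$charged) > 0,
                          logical(1)))
  if (length(chg_res) > 1) {
    for (u in seq_along(chg_res)[-1]) for (v in seq_len(u - 1)) {
      ri <- chg_res[u]; rj <- chg_res[v]
      if (adj_res[ri, rj]) next
      ai <- off[ri] + blocks[[ri]]$charged
      aj <- off[rj] + blocks[[rj]]$charged
      dmin <- min(D[ai, aj])
      if (dmin >= model$pair_distance_cutoff) next
      s <- if (dmin <= model$pair_switch_start) 1 else
        (model$pair_distance_cutoff - dmin) /
        (model$pair_distance_cutoff - model$pair_switch_start)
      sgn <- AA_FORMAL_CHARGE[blocks[[ri]]$aa] *
        AA_FORMAL_CHARGE[blocks[[rj]]$aa]
      e_pair <- e_pair + sign(sgn) * 0.5 * s
    }
  }
  # hydrogen bonds
  don <- do.call(rbind, lapply(seq_len(nres), function(i) {
    d <- blocks[[i]]$don
    if (is.null(d)) NULL else cbind(d[, 1] + off[i], d[, 2] + off[i], d[, 3])
  }))
  acc <- do.call(rbind, lapply(seq_len(nres), function(i) {
    ac <- blocks[[i]]$acc
    if (is.null(ac)) NULL else cbind(ac[, 1] + off[i], ac[, 2] + off[i],
                                     ac[, 3])
  }))
  e_hb_sc <- 0; e_hb_bb <- 0
  if (!is.null(don) && !is.null(acc)) {
    nd <- nrow(don); na_ <- nrow(acc)
    di <- rep(seq_len(nd), times = na_)
    ai <- rep(seq_len(na_), each = nd)
    d_res <- res[don[di, 1]]; a_res <- res[acc[ai, 1]]
    keep <- d_res != a_res & !(don[di, 3] == 1L & acc[ai, 3] == 1L) &
      !adj_res[cbind(d_res, a_res)]
    sel <- which(keep)
    if (length(sel)) {
      dv <- xyz[acc[ai[sel], 1], , drop = FALSE] -
        xyz[don[di[sel], 1], , drop = FALSE]
      dd <- sqrt(rowSums(dv * dv))
      inr <- dd >= model$hbond_dmin & dd <= model$hbond_dmax
      sel <- sel[inr]; dd <- dd[inr]
      if (length(sel)) {
        bv <- xyz[don[di[sel], 2], , drop = FALSE] -
          xyz[don[di[sel], 1], , drop = FALSE]
        av <- xyz[acc[ai[sel], 1], , drop = FALSE] -
          xyz[don[di[sel], 1], , drop = FALSE]
        cosang <- rowSums(bv * av) /
          (sqrt(rowSums(bv * bv)) * sqrt(rowSums(av * av)))
        f <- pmax(0, -pmax(-1, pmin(1, cosang)))^2
        e_raw <- -.hb_ramp(dd, model) * f
        isbb <- don[di[sel], 3] == 1L | acc[ai[sel], 3] == 1L
        e_hb_bb <- sum(e_raw[isbb])
        e_hb_sc <- sum(e_raw[!isbb])
      }
    }
  }
  e_rot <- sum(vapply(blocks, `[[`, numeric(1), "logp"))
  e_ref <- sum(model$reference_energies[
    vapply(blocks, `[[`, character(1), "aa")])
  w <- model$weights
  unname(w[["fa_atr"]] * e_atr + w[["fa_rep"]] * e_rep +
           w[["fa_sol"]] * e_sol + w[["fa_pair"]] * e_pair +
           w[["hbond_bb_sc"]] * e_hb_bb + w[["hbond_sc"]] * e_hb_sc +
           w[["rotamer"]] * e_rot + w[["reference"]] * e_ref)
}
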