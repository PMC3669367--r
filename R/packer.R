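# Fixed-backbone side-chain placement: the design task encodes which sites
# may change and to what types (with the preservation rules), packing is
# simulated annealing over discrete (type, rotamer) choices with Metropolis
# acceptance, and an exhaustive enumerator serves as optimality oracle on
# small instances.

#' Build a design task
#'
#' Marks every residue as designable or fixed and records why fixed sites
#' are preserved. Designable sites are the surface sites minus those caught
#' by the preservation rules:
#' * `glyprocys` - glycine, proline and cysteine are never mutated;
#' * `correct_charge` - residues already bearing the desired charge
#'   (Arg/Lys under positive polarity, Asp/Glu under negative);
#' * `hbonded_sidechain` - side chains participating in a hydrogen bond
#'   stronger than the model's preservation threshold;
#' * `resfile_excluded` - positions the user excluded via residue file;
#' * `not_surface` - everything not classified as surface.
#' Each rule can be switched off. Allowed types at a designable site are the
#' native type plus the charged types enabled by the `include_*` flags.
#'
#' @param structure A [protein_structure()].
#' @param surface Character vector of surface site keys
#'   (from [classify_surface()]).
#' @param polarity `"positive"` or `"negative"`.
#' @param model An [energy_model()] (supplies the hydrogen-bond
#'   preservation threshold).
#' @param include_arg,include_lys,include_asp,include_glu Charged types the
#'   packer may introduce (positive: Arg/Lys; negative: Asp/Glu).
#' @param preserve_glyprocys,preserve_hbonded_sidechains,preserve_correct_charge
#'   Toggle the individual preservation rules.
#' @param resfile Optional path to a residue file (see [read_resfile()]).
#' @param design_chain Restrict design to one chain (default: all sites in
#'   `surface`).
#' @return data.frame of class `design_task`: one row per residue with
#'   `designable`, `reason` (NA when designable) and list-column `allowed`.
#' @export
build_design_task <- function(structure, surface,
                              polarity = c("positive", "negative"),
                              model = energy_model(),
                              include_arg = FALSE, include_lys = FALSE,
                              include_asp = FALSE, include_glu = FALSE,
                              preserve_glyprocys = TRUE,
                              preserve_hbonded_sidechains = TRUE,
                              preserve_correct_charge = TRUE,
                              resfile = NULL, design_chain = NULL) {
  polarity <- match.arg(polarity)
  rt <- residue_sites(structure)
  if (length(setdiff(surface, rt$key)))
    stop("surface contains unknown sites: ",
         paste(setdiff(surface, rt$key), collapse = ", "), call. = FALSE)
  charged_types <- if (polarity == "positive") {
    c(if (include_lys) "K", if (include_arg) "R")
  } else {
    c(if (include_asp) "D", if (include_glu) "E")
  }
  correct <- if (polarity == "positive") c("R", "K") else c("D", "E")
  res_tab <- if (!is.null(resfile)) read_resfile(resfile) else NULL
  if (!is.null(res_tab)) {
    res_keys <- .site_key(res_tab$chain, res_tab$number)
    unknown <- setdiff(res_keys, rt$key)
    if (length(unknown))
      stop("residue file names sites absent from the structure: ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  hb_preserved <- character(0)
  if (preserve_hbonded_sidechains) {
    hb <- detect_sidechain_hbonds(structure, model)
    strong <- hb[hb$energy < model$hbond_preserve_threshold, , drop = FALSE]
    if (nrow(strong)) {
      don_sc <- strong$donor_key[!(strong$donor_atom %in% BACKBONE_ATOMS)]
      acc_sc <- strong$acceptor_key[!(strong$acceptor_atom %in%
                                        BACKBONE_ATOMS)]
      hb_preserved <- unique(c(don_sc, acc_sc))
    }
  }
  n <- nrow(rt)
  designable <- logical(n)
  reason <- rep(NA_character_, n)
  allowed <- vector("list", n)
  for (i in seq_len(n)) {
    key <- rt$key[i]; aa <- rt$aa[i]
    pick <- NULL
    if (!is.null(res_tab)) {
      j <- match(key, .site_key(res_tab$chain, res_tab$number))
      if (!is.na(j)) {
        if (res_tab$mode[j] == "NATRO") { reason[i] <- "resfile_excluded" }
        else pick <- strsplit(res_tab$aas[j], "")[[1]]
      }
    }
    if (is.na(reason[i]) && !(key %in% surface)) reason[i] <- "not_surface"
    if (is.na(reason[i]) && !is.null(design_chain) &&
        !(rt$chain[i] %in% design_chain)) reason[i] <- "not_surface"
    if (is.na(reason[i]) && preserve_glyprocys && aa %in% c("G", "P", "C"))
      reason[i] <- "glyprocys"
    if (is.na(reason[i]) && preserve_correct_charge && aa %in% correct)
      reason[i] <- "correct_charge"
    if (is.na(reason[i]) && key %in% hb_preserved)
      reason[i] <- "hbonded_sidechain"
    if (is.na(reason[i])) {
      designable[i] <- TRUE
      alw <- unique(c(aa, charged_types))
      if (!is.null(pick)) alw <- unique(c(aa, intersect(alw, pick)))
      allowed[[i]] <- alw
    } else {
      allowed[[i]] <- aa
    }
  }
  out <- rt
  out$designable <- designable
  out$reason <- reason
  out$allowed <- allowed
  class(out) <- c("design_task", class(out))
  out
}

# Enumerate the (type, rotamer) choices of every designable site and
# prebuild the corresponding residue atom blocks (data.frame form for the
# final structure, compact form for the proposal-loop scorer). Choice 1 is
# always the current (native) conformation.
.pack_choices <- function(structure, task, rotamers) {
  a <- structure$atoms
  blocks <- split(a, a$res_index)
  names(blocks) <- NULL
  cblocks <- lapply(blocks, .compact_block, rotamers = rotamers)
  design_idx <- which(task$designable)
  choices <- list()
  for (i in design_idx) {
    res <- blocks[[i]]
    bb <- res[res$atom %in% BACKBONE_ATOMS, , drop = FALSE]
    pn <- unlist(res[res$atom == "N", c("x", "y", "z")])
    pca <- unlist(res[res$atom == "CA", c("x", "y", "z")])
    pc <- unlist(res[res$atom == "C", c("x", "y", "z")])
    blk <- list(res)  # current conformation
    cblk <- list(cblocks[[i]])
    lab <- data.frame(aa = res$aa[1], rot = 0L, stringsAsFactors = FALSE)
    for (aa in task$allowed[[i]]) {
      lib <- rotamers[[aa]]
      for (r in seq_len(max(1L, nrow(lib$chi)))) {
        chis <- if (ncol(lib$chi)) lib$chi[r, ] else numeric(0)
        sc <- .build_sidechain(aa, pn, pca, pc, chis)
        nb <- bb
        nb$resid <- AA1TO3[[aa]]; nb$aa <- aa
        if (nrow(sc)) {
          add <- data.frame(chain = res$chain[1], resno = res$resno[1],
                            icode = res$icode[1], resid = AA1TO3[[aa]],
                            atom = sc$atom, x = sc$x, y = sc$y, z = sc$z,
                            aa = aa, elem = sc$elem, backbone = FALSE,
                            res_index = i, stringsAsFactors = FALSE)
          nb <- rbind(nb, add[, names(nb)])
        }
        blk[[length(blk) + 1]] <- nb
        cblk[[length(cblk) + 1]] <-
          .compact_block(nb, rotamers, logp = -log(lib$p[r]))
        lab <- rbind(lab, data.frame(aa = aa, rot = r,
                                     stringsAsFactors = FALSE))
      }
    }
    choices[[length(choices) + 1]] <-
      list(res_index = i, blocks = blk, cblocks = cblk, labels = lab)
  }
  rt <- residue_sites(structure)
  list(base = blocks, cbase = cblocks, design_idx = design_idx,
       choices = choices, chain = rt$chain, resno = rt$number)
}

.assemble_structure <- function(base_blocks, structure) {
  out <- structure
  atoms <- do.call(rbind, base_blocks)
  rownames(atoms) <- NULL
  out$atoms <- atoms
  out
}

#' Pack side chains by simulated annealing
#'
#' Monte Carlo optimization over the (type, rotamer) choices of the
#' designable sites: uniform random proposals with Metropolis acceptance
#' under a geometric cooling schedule (`kT` from `kT_hi` to `kT_lo` over
#' `sweeps` x total-choice-count proposals). Fixed sites never change; the
#' native type and conformation are always in the choice set, and the
#' best-encountered assignment is returned. Runs with equal seeds are
#' identical.
#'
#' @param structure A [protein_structure()].
#' @param task A [build_design_task()] result.
#' @param model An [energy_model()].
#' @param seed Integer seed (reproducibility contract).
#' @param schedule list with `kT_hi`, `kT_lo`, `sweeps`.
#' @param rotamers Rotamer library.
#' @return list with `structure` (best found), `energy`, `assignment`
#'   (data.frame site/aa/rotamer), `n_proposals`.
#' @export
pack_rotamers <- function(structure, task, model = energy_model(),
                          seed = 1L,
                          schedule = list(kT_hi = 10, kT_lo = 0.3,
                                          sweeps = 30),
                          rotamers = default_rotamers()) {
  pc <- .pack_choices(structure, task, rotamers)
  if (!length(pc$choices)) {
    sc <- score_structure(structure, model, rotamers)
    return(list(structure = structure, energy = sc$total,
                assignment = data.frame(), n_proposals = 0L))
  }
  nch <- vapply(pc$choices, function(ch) length(ch$blocks), integer(1))
  total_choices <- sum(nch)
  n_prop <- as.integer(schedule$sweeps * total_choices)
  kts <- schedule$kT_hi *
    (schedule$kT_lo / schedule$kT_hi)^(seq(0, 1, length.out = n_prop))
  cur_cb <- pc$cbase
  cur_assign <- rep(1L, length(pc$choices))
  cur_e <- .score_compact(cur_cb, pc$chain, pc$resno, model)
  best_assign <- cur_assign; best_e <- cur_e
  .with_seed(seed, {
    for (t in seq_len(n_prop)) {
      si <- sample.int(length(pc$choices), 1)
      ci <- sample.int(nch[si], 1)
      if (ci == cur_assign[si]) next
      cand_cb <- cur_cb
      cand_cb[[pc$choices[[si]]$res_index]] <- pc$choices[[si]]$cblocks[[ci]]
      cand_e <- .score_compact(cand_cb, pc$chain, pc$resno, model)
      de <- cand_e - cur_e
      if (de <= 0 || stats::runif(1) < exp(-de / kts[t])) {
        cur_cb <- cand_cb; cur_e <- cand_e; cur_assign[si] <- ci
        if (cur_e < best_e - 1e-12) {
          best_e <- cur_e
          best_assign <- cur_assign
        }
      }
    }
  })
  best_blocks <- pc$base
  for (k in seq_along(pc$choices))
    best_blocks[[pc$choices[[k]]$res_index]] <-
      pc$choices[[k]]$blocks[[best_assign[k]]]
  assignment <- do.call(rbind, lapply(seq_along(pc$choices), function(k) {
    lab <- pc$choices[[k]]$labels[best_assign[k], ]
    data.frame(key = task$key[pc$choices[[k]]$res_index], aa = lab$aa,
               rotamer = lab$rot, stringsAsFactors = FALSE)
  }))
  list(structure = .assemble_structure(best_blocks, structure),
       energy = best_e, assignment = assignment, n_proposals = n_prop)
}

#' Exhaustively enumerate a small design task
#'
#' Global optimum by full enumeration of the (type, rotamer) grid; refuses
#' search spaces above `max_states` with a size report. Oracle for
#' [pack_rotamers()] on small instances.
#'
#' @inheritParams pack_rotamers
#' @param max_states Enumeration bound.
#' @return list with `structure`, `energy`, `assignment`, `n_states`.
#' @export
exhaustive_pack <- function(structure, task, model = energy_model(),
                            rotamers = default_rotamers(),
                            max_states = 1e5) {
  pc <- .pack_choices(structure, task, rotamers)
  if (!length(pc$choices)) {
    sc <- score_structure(structure, model, rotamers)
    return(list(structure = structure, energy = sc$total,
                assignment = data.frame(), n_states = 1L))
  }
  nch <- vapply(pc$choices, function(ch) length(ch$blocks), integer(1))
  n_states <- prod(nch)
  if (n_states > max_states)
    stop("search space too large for exhaustive enumeration: ",
         format(n_states, big.mark = ","), " states (limit ",
         format(max_states, big.mark = ","), ")", call. = FALSE)
  grid <- expand.grid(lapply(nch, seq_len), KEEP.OUT.ATTRS = FALSE)
  best_e <- Inf; best_assign <- NULL
  for (g in seq_len(nrow(grid))) {
    cb <- pc$cbase
    for (k in seq_along(pc$choices))
      cb[[pc$choices[[k]]$res_index]] <-
        pc$choices[[k]]$cblocks[[grid[g, k]]]
    e <- .score_compact(cb, pc$chain, pc$resno, model)
    if (e < best_e - 1e-12) {
      best_e <- e; best_assign <- as.integer(grid[g, ])
    }
  }
  best_blocks <- pc$base
  for (k in seq_along(pc$choices))
    best_blocks[[pc$choices[[k]]$res_index]] <-
      pc$choices[[k]]$blocks[[best_assign[k]]]
  assignment <- do.call(rbind, lapply(seq_along(pc$choices), function(k) {
    lab <- pc$choices[[k]]$labels[best_assign[k], ]
    data.frame(key = task$key[pc$choices[[k]]$res_index], aa = lab$aa,
               rotamer = lab$rot, stringsAsFactors = FALSE)
  }))
  list(structure = .assemble_structure(best_blocks, structure),
       energy = best_e, assignment = assignment, n_states = n_states)
}

# --- residue file (resfile) dialect ----------------------------------------

#' Read a residue file
#'
#' Line-oriented dialect: a `start` header, then one directive per line,
#' either `<resnum> <chain> NATRO` (position fixed) or
#' `<resnum> <chain> PIKAA <letters>` (allowed amino-acid set).
#'
#' @param path Path to the residue file.
#' @return data.frame with columns `number`, `chain`, `mode`, `aas`.
#' @export
read_resfile <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines) || tolower(lines[1]) != "start")
    stop("residue file must begin with a 'start' line", call. = FALSE)
  body <- lines[-1]
  out <- lapply(body, function(ln) {
    f <- strsplit(ln, "[[:space:]]+")[[1]]
    if (length(f) < 3 || !(toupper(f[3]) %in% c("NATRO", "PIKAA")))
      stop("malformed residue file line: ", ln, call. = FALSE)
    mode <- toupper(f[3])
    if (mode == "PIKAA" && length(f) < 4)
      stop("PIKAA line without amino-acid letters: ", ln, call. = FALSE)
    data.frame(number = as.integer(f[1]), chain = f[2], mode = mode,
               aas = if (mode == "PIKAA") f[4] else "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write a residue file from a design task
#'
#' Designable sites become `PIKAA` lines with their allowed types; fixed
#' sites become `NATRO` lines. Feeding the file back into
#' [build_design_task()] reproduces the same designable-site set.
#'
#' @param task A [build_design_task()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_resfile <- function(task, path) {
  lines <- "start"
  for (i in seq_len(nrow(task))) {
    lines <- c(lines, if (task$designable[i])
      paste(task$number[i], task$chain[i], "PIKAA",
            paste(sort(task$allowed[[i]]), collapse = ""))
      else paste(task$number[i], task$chain[i], "NATRO"))
  }
  writeLines(lines, path)
  invisible(path)
}
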