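# Atomic data model: a ProteinStructure is an ordered table of heavy atoms
# grouped into residue sites, with the filtering behavior the supercharging
# protocols assume (canonical residues only, first altloc, no hydrogens,
# ligands and waters ignored).

#' Construct a ProteinStructure from an atom table
#'
#' The atom table must contain one row per heavy atom with columns `chain`,
#' `resno`, `icode`, `resid` (three-letter code), `atom` (PDB atom name),
#' `x`, `y`, `z`. Residues must be contiguous blocks in file order; every
#' residue needs backbone N, CA and C. Non-finite coordinates are rejected.
#'
#' @param atoms data.frame as described above.
#' @param source_name Label carried through to reports and output names.
#' @return An object of class `ProteinStructure`.
#' @export
protein_structure <- function(atoms, source_name = "structure") {
  req <- c("chain", "resno", "icode", "resid", "atom", "x", "y", "z")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("atom table lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  atoms$chain <- as.character(atoms$chain)
  atoms$resno <- as.integer(atoms$resno)
  atoms$icode <- ifelse(is.na(atoms$icode), "", as.character(atoms$icode))
  atoms$resid <- as.character(atoms$resid)
  atoms$atom <- as.character(atoms$atom)
  if (nrow(atoms) == 0) stop("empty atom table", call. = FALSE)
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite atom coordinates", call. = FALSE)
  if (!all(atoms$resid %in% names(AA3TO1)))
    stop("non-canonical residue types present: ",
         paste(unique(setdiff(atoms$resid, names(AA3TO1))), collapse = ", "),
         call. = FALSE)
  atoms$aa <- unname(AA3TO1[atoms$resid])
  atoms$elem <- .atom_element(atoms$atom)
  atoms$backbone <- atoms$atom %in% BACKBONE_ATOMS
  key <- paste(atoms$chain, atoms$resno, atoms$icode, sep = "\r")
  ukey <- unique(key)
  # each residue site must appear as exactly one contiguous atom block
  blocks <- rle(key)$values
  if (length(blocks) != length(ukey))
    stop("residue sites not unique / atoms not contiguous", call. = FALSE)
  atoms$res_index <- match(key, ukey)
  for (i in seq_along(ukey)) {
    sub <- atoms$atom[atoms$res_index == i]
    if (!all(c("N", "CA", "C") %in% sub))
      stop("residue ", gsub("\r", ":", ukey[i]),
           " lacks backbone N/CA/C", call. = FALSE)
    if (anyDuplicated(sub))
      stop("duplicate atom names in residue ", gsub("\r", ":", ukey[i]),
           call. = FALSE)
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, source_name = source_name),
            class = "ProteinStructure")
}

.atom_element <- function(atom_name) {
  first <- substr(gsub("^[0-9']+", "", atom_name), 1, 1)
  ifelse(first %in% c("C", "N", "O", "S"), first, "C")
}

#' @export
print.ProteinStructure <- function(x, ...) {
  rt <- residue_sites(x)
  cat("ProteinStructure '", x$source_name, "': ", nrow(rt), " residues, ",
      nrow(x$atoms), " heavy atoms, chains ",
      paste(unique(rt$chain), collapse = ","), "\n", sep = "")
  cat("net formal charge: ", sprintf("%+d", net_formal_charge(x)), "\n",
      sep = "")
  invisible(x)
}

#' Residue sites of a structure
#'
#' @param structure A [protein_structure()].
#' @return data.frame with one row per residue: `chain`, `number`, `icode`,
#'   `aa` (one-letter), and `key` (the compact `chain:number[:icode]` site
#'   label accepted wherever a site argument is expected).
#' @export
residue_sites <- function(structure) {
  stopifnot(inherits(structure, "ProteinStructure"))
  a <- structure$atoms
  first <- !duplicated(a$res_index)
  data.frame(chain = a$chain[first], number = a$resno[first],
             icode = a$icode[first], aa = a$aa[first],
             key = .site_key(a$chain[first], a$resno[first], a$icode[first]),
             stringsAsFactors = FALSE)
}

.site_key <- function(chain, number, icode = "") {
  ifelse(is.na(icode) | icode == "",
         paste(chain, number, sep = ":"),
         paste(chain, number, icode, sep = ":"))
}

# Resolve a site argument (character "A:12[:B]", or list(chain, number,
# icode)) to a residue index; error when absent.
.resolve_site <- function(structure, site) {
  rt <- residue_sites(structure)
  if (is.character(site) && length(site) == 1) {
    i <- match(site, rt$key)
  } else if (is.list(site)) {
    icode <- if (is.null(site$icode)) "" else site$icode
    i <- match(.site_key(site$chain, site$number, icode), rt$key)
  } else stop("invalid site specification", call. = FALSE)
  if (is.na(i)) stop("no such residue site: ",
                     if (is.character(site)) site else
                       .site_key(site$chain, site$number,
                                 if (is.null(site$icode)) "" else site$icode),
                     call. = FALSE)
  i
}

#' Read a protein structure from a PDB file
#'
#' Parses ATOM records through \pkg{bio3d} and applies the filtering the
#' design protocols assume: HETATM records (waters, ligands, and any
#' unrecognized residue) are ignored, hydrogens are discarded, only the first
#' alternate location is kept, and residues missing backbone N/CA/C are
#' dropped with a warning. Only the first model of a multi-model file is
#' read.
#'
#' @param path Path to a PDB file.
#' @param chain_filter Optional chain identifier(s); other chains are
#'   discarded.
#' @return A [protein_structure()].
#' @export
read_pdb <- function(path, chain_filter = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  p <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = TRUE,
                                        verbose = FALSE))
  at <- p$atom[p$atom$type == "ATOM", , drop = FALSE]
  at <- at[at$resid %in% names(AA3TO1), , drop = FALSE]
  if (nrow(at) == 0)
    stop("no canonical-residue ATOM records in ", path, call. = FALSE)
  if (any(is.na(at$chain) | at$chain == ""))
    stop("ATOM records without a chain identifier in ", path, call. = FALSE)
  elem <- ifelse(!is.na(at$elesy) & at$elesy != "", at$elesy,
                 .atom_element(at$elety))
  at <- at[!(elem %in% c("H", "D")), , drop = FALSE]
  at <- at[!grepl("^[0-9]*H", at$elety), , drop = FALSE]
  if (!is.null(chain_filter)) {
    at <- at[at$chain %in% chain_filter, , drop = FALSE]
    if (nrow(at) == 0)
      stop("no atoms left after chain filter in ", path, call. = FALSE)
  }
  icode <- ifelse(is.na(at$insert), "", at$insert)
  key <- paste(at$chain, at$resno, icode, sep = "\r")
  # drop residues lacking a complete backbone
  ok <- vapply(split(at$elety, key), function(s) all(c("N", "CA", "C") %in% s),
               logical(1))
  bad <- names(ok)[!ok]
  if (length(bad)) {
    warning("dropping ", length(bad), " residue(s) missing backbone N/CA/C: ",
            paste(gsub("\r", ":", bad), collapse = ", "), call. = FALSE)
    at <- at[!(key %in% bad), , drop = FALSE]
  }
  # first occurrence wins for duplicated atom names (residual altlocs)
  key <- paste(at$chain, at$resno, ifelse(is.na(at$insert), "", at$insert),
               sep = "\r")
  at <- at[!duplicated(paste(key, at$elety, sep = "\r")), , drop = FALSE]
  if (nrow(at) == 0)
    stop("structure empty after filtering: ", path, call. = FALSE)
  atoms <- data.frame(chain = at$chain, resno = at$resno,
                      icode = ifelse(is.na(at$insert), "", at$insert),
                      resid = at$resid, atom = at$elety,
                      x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE)
  protein_structure(atoms, source_name = sub("\\.pdb$", "", basename(path),
                                             ignore.case = TRUE))
}

#' Write a structure to a PDB file
#'
#' Emits standard fixed-width ATOM records with one TER record per chain,
#' coordinates rounded to three decimals.
#'
#' @param structure A [protein_structure()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(structure, path) {
  stopifnot(inherits(structure, "ProteinStructure"))
  a <- structure$atoms
  xyz <- as.numeric(t(as.matrix(a[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = round(xyz, 3),
                   type = rep("ATOM", nrow(a)),
                   resno = a$resno, resid = a$resid,
                   eleno = seq_len(nrow(a)), elety = a$atom,
                   chain = a$chain,
                   insert = ifelse(a$icode == "", NA, a$icode),
                   o = rep(1, nrow(a)), b = rep(0, nrow(a)),
                   elesy = a$elem, chainter = TRUE)
  invisible(path)
}

#' Net formal charge of a structure
#'
#' Counts charged side chains: (Arg + Lys) - (Asp + Glu). Histidine is
#' treated as neutral and chain termini are ignored.
#'
#' @param structure A [protein_structure()].
#' @return Integer net charge.
#' @export
#' @examples
#' s <- make_structure("DEKR")
#' net_formal_charge(s)  # 0
net_formal_charge <- function(structure) {
  aa <- residue_sites(structure)$aa
  sum(vapply(aa, function(x) {
    v <- AA_FORMAL_CHARGE[x]
    if (is.na(v)) 0L else as.integer(v)
  }, integer(1)))
}

#' Mutate one residue site
#'
#' Replaces the side chain at `site` with the template geometry of the
#' lowest-clash rotamer of `new_aa`, built on the unchanged backbone. Clash
#' is measured as the Lennard-Jones repulsion of the candidate side chain
#' against all atoms of other (non-bonded-neighbor) residues. The input
#' structure is not modified.
#'
#' @param structure A [protein_structure()].
#' @param site Site label `"chain:number[:icode]"` or
#'   `list(chain=, number=, icode=)`.
#' @param new_aa One-letter amino-acid code to mutate to.
#' @param rotamers Rotamer library, see [default_rotamers()].
#' @param model Energy model used for the clash score, see [energy_model()].
#' @return A new `ProteinStructure`.
#' @export
mutate_residue <- function(structure, site, new_aa,
                           rotamers = default_rotamers(),
                           model = energy_model()) {
  stopifnot(inherits(structure, "ProteinStructure"))
  .assert_aa(new_aa)
  i <- .resolve_site(structure, site)
  a <- structure$atoms
  res <- a[a$res_index == i, , drop = FALSE]
  bb <- res[res$atom %in% BACKBONE_ATOMS, , drop = FALSE]
  pn <- unlist(res[res$atom == "N", c("x", "y", "z")])
  pca <- unlist(res[res$atom == "CA", c("x", "y", "z")])
  pc <- unlist(res[res$atom == "C", c("x", "y", "z")])
  lib <- rotamers[[new_aa]]
  nrot <- max(1L, nrow(lib$chi))
  best <- NULL; best_clash <- Inf
  for (r in seq_len(nrot)) {
    chis <- if (ncol(lib$chi)) lib$chi[r, ] else numeric(0)
    sc <- .build_sidechain(new_aa, pn, pca, pc, chis)
    clash <- .sidechain_clash(sc, structure, i, model)
    if (clash < best_clash - 1e-12) {
      best_clash <- clash
      best <- sc
    }
  }
  new_res <- bb
  new_res$resid <- AA1TO3[new_aa]
  new_res$aa <- new_aa
  if (nrow(best)) {
    add <- data.frame(chain = res$chain[1], resno = res$resno[1],
                      icode = res$icode[1], resid = AA1TO3[[new_aa]],
                      atom = best$atom, x = best$x, y = best$y, z = best$z,
                      aa = new_aa, elem = best$elem, backbone = FALSE,
                      res_index = i, stringsAsFactors = FALSE)
    new_res <- rbind(new_res, add[, names(new_res)])
  }
  parts <- split(a, a$res_index)
  parts[[as.character(i)]] <- new_res
  out <- do.call(rbind, parts[order(as.integer(names(parts)))])
  rownames(out) <- NULL
  res_structure <- structure
  res_structure$atoms <- out
  res_structure
}

#' Concatenate two structures
#'
#' Appends the residues of `b` after those of `a`; residue sites must remain
#' unique. Used to assemble multi-segment and multi-chain fixtures.
#'
#' @param a,b [protein_structure()] objects.
#' @return A combined `ProteinStructure` named after `a`.
#' @export
merge_structures <- function(a, b) {
  stopifnot(inherits(a, "ProteinStructure"), inherits(b, "ProteinStructure"))
  cols <- c("chain", "resno", "icode", "resid", "atom", "x", "y", "z")
  atoms <- rbind(a$atoms[, cols], b$atoms[, cols])
  protein_structure(atoms, source_name = a$source_name)
}

# One-letter sequence indexed by site key.
.sequence_by_key <- function(structure) {
  rt <- residue_sites(structure)
  stats::setNames(rt$aa, rt$key)
}
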