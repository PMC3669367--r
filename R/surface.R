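# Surface definitions used by the two supercharging protocols:
#  * atom-based - the AvNAPSA value, the Average number of Neighboring Atoms
#    Per Side-chain Atom (10 Angstrom cutoff); low values mean high solvent
#    exposure;
#  * residue-based - the count of neighboring residues with Cbeta-Cbeta
#    distance under 10 Angstrom (Calpha surrogate for glycine).
# Neighbor counting is over heavy atoms of *other* residues, backbone
# included; the residue's own atoms never count.

.AVNAPSA_NEIGHBOR_DIST <- 10

#' AvNAPSA value of one residue site
#'
#' Mean, over the site's side-chain heavy atoms, of the number of heavy atoms
#' belonging to other residues within 10 Angstrom. Glycine (no side chain)
#' has no AvNAPSA value and raises an error; callers must skip it.
#'
#' @param structure A [protein_structure()].
#' @param site Site label `"chain:number[:icode]"` or list.
#' @return Numeric AvNAPSA value (>= 0).
#' @export
avnapsa_value <- function(structure, site) {
  i <- .resolve_site(structure, site)
  v <- unname(.avnapsa_all(structure)[i])
  if (is.na(v))
    stop("AvNAPSA value undefined: residue has no side-chain atoms",
         call. = FALSE)
  v
}

# Vectorized AvNAPSA for all residues; NA where undefined (no side-chain
# atoms).
.avnapsa_all <- function(structure) {
  a <- structure$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  D <- as.matrix(stats::dist(xyz))
  foreign <- outer(a$res_index, a$res_index, "!=")
  counts <- rowSums(D < .AVNAPSA_NEIGHBOR_DIST & foreign)
  nres <- max(a$res_index)
  out <- rep(NA_real_, nres)
  sc <- !a$backbone
  for (i in seq_len(nres)) {
    sel <- sc & a$res_index == i
    if (any(sel)) out[i] <- mean(counts[sel])
  }
  out
}

#' Residue neighbor count (Cbeta-based)
#'
#' Number of other residues whose Cbeta lies within 10 Angstrom of the
#' site's Cbeta; glycine contributes its Calpha as surrogate. Insensitive to
#' side-chain conformation and sequence changes beyond Cbeta.
#'
#' @inheritParams avnapsa_value
#' @return Integer count (>= 0).
#' @export
residue_neighbor_count <- function(structure, site) {
  i <- .resolve_site(structure, site)
  unname(.neighbor_count_all(structure)[i])
}

.cbeta_coords <- function(structure) {
  a <- structure$atoms
  nres <- max(a$res_index)
  out <- matrix(NA_real_, nres, 3)
  for (i in seq_len(nres)) {
    rows <- a[a$res_index == i, ]
    j <- match("CB", rows$atom)
    if (is.na(j)) j <- match("CA", rows$atom)
    out[i, ] <- c(rows$x[j], rows$y[j], rows$z[j])
  }
  out
}

.neighbor_count_all <- function(structure) {
  cb <- .cbeta_coords(structure)
  D <- as.matrix(stats::dist(cb))
  as.integer(rowSums(D < .AVNAPSA_NEIGHBOR_DIST) - 1L)
}

#' Classify surface residues
#'
#' Atom-based mode marks sites with AvNAPSA value strictly below `cutoff`
#' (default 120; glycine is always excluded since it has no AvNAPSA value).
#' Residue-based mode marks sites with fewer than `cutoff` (default 16)
#' Cbeta neighbors within 10 Angstrom. Extended-surface variants (cutoffs of
#' 200 and 30, to include peripheral or partially buried residues) are the
#' same code path with a larger cutoff.
#'
#' @param structure A [protein_structure()].
#' @param mode `"atom_based"` or `"residue_based"`.
#' @param cutoff Positive threshold; strict `<` comparison in both modes.
#' @return Character vector of surface site keys (see [residue_sites()]).
#' @export
classify_surface <- function(structure,
                             mode = c("atom_based", "residue_based"),
                             cutoff = if (match.arg(mode) == "atom_based")
                               120 else 16) {
  mode <- match.arg(mode)
  if (!is.numeric(cutoff) || cutoff <= 0)
    stop("cutoff must be positive", call. = FALSE)
  ann <- surface_annotation(structure, atom_cutoff = if (mode == "atom_based")
    cutoff else 120, residue_cutoff = if (mode == "residue_based") cutoff
    else 16)
  if (mode == "atom_based") ann$key[ann$is_surface_atom_based]
  else ann$key[ann$is_surface_residue_based]
}

#' Per-residue surface annotation table
#'
#' @param structure A [protein_structure()].
#' @param atom_cutoff AvNAPSA surface cutoff (strict `<`).
#' @param residue_cutoff Cbeta neighbor-count surface cutoff (strict `<`).
#' @return data.frame with one row per site: `chain`, `number`, `icode`,
#'   `aa`, `key`, `avnapsa` (NA for glycine), `neighbor_count`,
#'   `is_surface_atom_based`, `is_surface_residue_based`.
#' @export
surface_annotation <- function(structure, atom_cutoff = 120,
                               residue_cutoff = 16) {
  rt <- residue_sites(structure)
  av <- .avnapsa_all(structure)
  nc <- .neighbor_count_all(structure)
  rt$avnapsa <- av
  rt$neighbor_count <- nc
  rt$is_surface_atom_based <- !is.na(av) & av < atom_cutoff
  rt$is_surface_residue_based <- nc < residue_cutoff
  rt
}

#' Write a surface annotation table as TSV
#'
#' @param structure A [protein_structure()].
#' @param path Output path.
#' @param ... Passed to [surface_annotation()].
#' @return Invisibly, `path`.
#' @export
write_surface_annotation <- function(structure, path, ...) {
  ann <- surface_annotation(structure, ...)
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
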