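# Internal-coordinate geometry: torsion/angle measurement, natural-extension
# (NeRF) atom placement, side-chain construction from the topology tables,
# chi-angle extraction, and rigid-body transforms.

.vnorm <- function(v) sqrt(sum(v * v))

.vunit <- function(v) {
  n <- .vnorm(v)
  if (n < 1e-12) stop("degenerate zero-length vector", call. = FALSE)
  v / n
}

.vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @noRd
.bond_angle <- function(p1, p2, p3) {
  u <- .vunit(p1 - p2); v <- .vunit(p3 - p2)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

# Signed torsion p1-p2-p3-p4 in degrees, IUPAC sign convention.
.torsion <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .vcross(b1, b2); n2 <- .vcross(b2, b3)
  m1 <- .vcross(n1, .vunit(b2))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

# NeRF placement: position of atom X bonded to c with bond length `bond`,
# angle b-c-X `angle` (degrees), torsion a-b-c-X `tors` (degrees).
.place_atom <- function(a, b, c, bond, angle, tors) {
  ang <- angle * pi / 180
  tor <- tors * pi / 180
  d <- c(-bond * cos(ang),
         bond * sin(ang) * cos(tor),
         -bond * sin(ang) * sin(tor))
  bc <- .vunit(c - b)
  n <- .vunit(.vcross(b - a, bc))
  m <- cbind(bc, .vcross(n, bc), n)
  as.numeric(m %*% d + c)
}

# Build the side-chain heavy atoms of `aa` onto a backbone frame given the
# N/CA/C positions and a chi-angle vector (degrees, recycled/truncated to the
# type's chi count).  Returns a data.frame(atom, elem, x, y, z); empty for
# glycine.
.build_sidechain <- function(aa, n_pos, ca_pos, c_pos, chis = numeric(0)) {
  .assert_aa(aa)
  if (aa == "G")
    return(data.frame(atom = character(0), elem = character(0),
                      x = numeric(0), y = numeric(0), z = numeric(0),
                      stringsAsFactors = FALSE))
  pos <- list(N = n_pos, CA = ca_pos, C = c_pos)
  rows <- rbind(CB_ROW, SIDECHAIN_TOPOLOGY[[aa]])
  out <- vector("list", nrow(rows))
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    tors <- if (!is.na(r$chi)) {
      if (r$chi > length(chis))
        stop("missing chi", r$chi, " for ", aa, call. = FALSE)
      chis[r$chi] + r$offset
    } else r$tors
    p <- .place_atom(pos[[r$a]], pos[[r$b]], pos[[r$c]], r$bond, r$angle, tors)
    pos[[r$atom]] <- p
    out[[i]] <- data.frame(atom = r$atom, elem = r$elem,
                           x = p[1], y = p[2], z = p[3],
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

.n_chi <- function(aa) {
  if (is.null(CHI_ATOMS[[aa]])) 0L else length(CHI_ATOMS[[aa]])
}

# Measure the chi angles of one residue from coordinates.  `atoms` is the
# residue's atom data.frame (atom, x, y, z).  Returns a numeric vector; NA for
# any chi whose defining atoms are missing.
.measure_chis <- function(atoms, aa) {
  defs <- CHI_ATOMS[[aa]]
  if (is.null(defs)) return(numeric(0))
  vapply(defs, function(q) {
    idx <- match(q, atoms$atom)
    if (anyNA(idx)) return(NA_real_)
    p <- lapply(idx, function(i) c(atoms$x[i], atoms$y[i], atoms$z[i]))
    .torsion(p[[1]], p[[2]], p[[3]], p[[4]])
  }, numeric(1))
}

.circ_diff <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}

# Nearest library rotamer for a measured chi vector; returns list(index, p).
# Residues with no rotatable chis (G, A) map to the single unit rotamer.
.nearest_rotamer <- function(aa, chis, rotamers = ROTAMER_LIBRARY) {
  lib <- rotamers[[aa]]
  if (is.null(lib) || nrow(lib$chi) == 0 || ncol(lib$chi) == 0 ||
      length(chis) == 0 || anyNA(chis))
    return(list(index = 1L, p = 1))
  d <- apply(lib$chi, 1, function(r) max(.circ_diff(chis, r)))
  i <- which.min(d)
  list(index = i, p = lib$p[i])
}

# --- rigid-body helpers -----------------------------------------------------

# Rotation matrix taking unit vector a onto unit vector b (Rodrigues).
.rotation_between <- function(a, b) {
  a <- .vunit(a); b <- .vunit(b)
  v <- .vcross(a, b)
  s <- .vnorm(v)
  co <- sum(a * b)
  if (s < 1e-12) {
    if (co > 0) return(diag(3))
    # antiparallel: rotate pi about any axis perpendicular to a
    axis <- .vunit(.vcross(a, if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)))
    K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                  axis[2], -axis[1], 0), 3, 3)
    return(diag(3) + 2 * K %*% K)
  }
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + K + K %*% K * ((1 - co) / s^2)
}

.axis_rotation <- function(axis, theta_deg) {
  axis <- .vunit(axis)
  th <- theta_deg * pi / 180
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Apply a rigid-body transform to a structure
#'
#' Rotates all coordinates by `rotation` and then translates by
#' `translation`. Useful for assembling crafted fixtures and for testing the
#' rigid-body invariance of geometric metrics.
#'
#' @param structure A [protein_structure()].
#' @param rotation 3x3 rotation matrix.
#' @param translation Length-3 numeric translation vector (Angstrom).
#' @return The transformed structure.
#' @export
transform_structure <- function(structure, rotation = diag(3),
                                translation = c(0, 0, 0)) {
  stopifnot(inherits(structure, "ProteinStructure"))
  xyz <- as.matrix(structure$atoms[, c("x", "y", "z")])
  xyz <- xyz %*% t(rotation)
  structure$atoms$x <- xyz[, 1] + translation[1]
  structure$atoms$y <- xyz[, 2] + translation[2]
  structure$atoms$z <- xyz[, 3] + translation[3]
  structure
}
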