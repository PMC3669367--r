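# Brute-force oracles and shared fixture helpers, kept deliberately naive
# and independent of the package's vectorized implementations.

# O(N^2) AvNAPSA oracle: explicit double loop over atoms.
oracle_avnapsa <- function(structure, key) {
  a <- structure$atoms
  rt <- residue_sites(structure)
  i <- match(key, rt$key)
  sc_rows <- which(a$res_index == i & !a$backbone)
  if (!length(sc_rows)) return(NA_real_)
  counts <- numeric(length(sc_rows))
  for (k in seq_along(sc_rows)) {
    p <- c(a$x[sc_rows[k]], a$y[sc_rows[k]], a$z[sc_rows[k]])
    cnt <- 0
    for (j in seq_len(nrow(a))) {
      if (a$res_index[j] == i) next
      q <- c(a$x[j], a$y[j], a$z[j])
      if (sqrt(sum((p - q)^2)) < 10) cnt <- cnt + 1
    }
    counts[k] <- cnt
  }
  mean(counts)
}

# O(N^2) Cbeta neighbor-count oracle.
oracle_neighbor_count <- function(structure, key) {
  a <- structure$atoms
  rt <- residue_sites(structure)
  rep_atom <- function(i) {
    rows <- a[a$res_index == i, ]
    j <- match("CB", rows$atom)
    if (is.na(j)) j <- match("CA", rows$atom)
    c(rows$x[j], rows$y[j], rows$z[j])
  }
  i <- match(key, rt$key)
  p <- rep_atom(i)
  cnt <- 0L
  for (j in seq_len(nrow(rt))) {
    if (j == i) next
    if (sqrt(sum((p - rep_atom(j))^2)) < 10) cnt <- cnt + 1L
  }
  cnt
}

# Naive Lennard-Jones sum (atr + rep) by explicit double loop, mirroring the
# model's published functional form but none of its vectorized code.
oracle_lj_total <- function(structure, model = energy_model()) {
  a <- structure$atoms
  rt <- residue_sites(structure)
  rad <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)
  eps <- c(C = 0.12, N = 0.16, O = 0.20, S = 0.25)
  tot_atr <- 0; tot_rep <- 0
  n <- nrow(a)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ri <- a$res_index[i]; rj <- a$res_index[j]
    if (ri == rj) next
    if (rt$chain[ri] == rt$chain[rj] &&
        abs(rt$number[ri] - rt$number[rj]) == 1) next
    if (a$backbone[i] && a$backbone[j]) next
    d <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 +
                (a$z[i] - a$z[j])^2)
    rmin <- rad[a$elem[i]] + rad[a$elem[j]]
    ee <- sqrt(eps[a$elem[i]] * eps[a$elem[j]])
    if (d >= rmin) {
      if (d <= model$atr_cutoff) {
        x6 <- (rmin / d)^6
        tot_atr <- tot_atr + ee * (x6^2 - 2 * x6)
      }
    } else {
      tot_atr <- tot_atr - ee
      cap <- model$rep_cap_frac * rmin
      if (d >= cap) {
        x6 <- (rmin / d)^6
        tot_rep <- tot_rep + ee * (x6^2 - 2 * x6) + ee
      } else {
        x6 <- (rmin / cap)^6
        val <- ee * (x6^2 - 2 * x6) + ee
        slope <- ee * 12 * (rmin^12 / cap^13 - rmin^6 / cap^7)
        tot_rep <- tot_rep + val + slope * (cap - d)
      }
    }
  }
  c(fa_atr = unname(tot_atr), fa_rep = unname(tot_rep))
}

random_rotation <- function(seed) {
  set.seed(seed)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# Random mixed-polarity sequence fixture (always includes mutation
# candidates of both signs).
random_fixture <- function(seed, n = 12) {
  set.seed(seed)
  pool <- c("A", "A", "S", "T", "V", "L", "N", "Q", "D", "E", "K", "R", "G")
  seqc <- paste(sample(pool, n, replace = TRUE), collapse = "")
  make_structure(seqc, backbone = sample(c("ideal_helix", "ideal_strand"), 1),
                 source_name = paste0("rand", seed))
}

# Seven-helix bundle with a buried center, for surface-definition tests.
bundle_fixture <- function() {
  core <- make_structure("AAAAAAAAAA", backbone = "ideal_helix",
                         chain = "A", start_resno = 1L,
                         source_name = "bundle")
  out <- core
  axis <- c(0, 0, 0)
  ca <- core$atoms[core$atoms$atom == "CA", c("x", "y", "z")]
  dirv <- as.numeric(ca[nrow(ca), ] - ca[1, ])
  dirv <- dirv / sqrt(sum(dirv^2))
  perp1 <- c(dirv[2], -dirv[1], 0); perp1 <- perp1 / sqrt(sum(perp1^2))
  perp2 <- c(dirv[2] * perp1[3] - dirv[3] * perp1[2],
             dirv[3] * perp1[1] - dirv[1] * perp1[3],
             dirv[1] * perp1[2] - dirv[2] * perp1[1])
  for (k in 1:6) {
    ang <- 2 * pi * k / 6
    shift <- 9.5 * (cos(ang) * perp1 + sin(ang) * perp2)
    seg <- make_structure("AAAAAAAAAA", backbone = "ideal_helix",
                          chain = LETTERS[k + 1], start_resno = 1L)
    out <- merge_structures(out, transform_structure(seg, diag(3), shift))
  }
  out
}

# Compact-path score, for the dual-route scoring equality checks.
compact_total <- function(structure, model = energy_model(),
                          rotamers = default_rotamers()) {
  blocks <- split(structure$atoms, structure$atoms$res_index)
  cb <- lapply(blocks, superchargeR:::.compact_block, rotamers = rotamers)
  rt <- residue_sites(structure)
  superchargeR:::.score_compact(cb, rt$chain, rt$number, model)
}

# Rotamer library trimmed to at most `k` rotamers per type (renormalized),
# to keep exhaustive search spaces tiny.
trimmed_rotamers <- function(k = 2) {
  lib <- default_rotamers()
  for (aa in names(lib)) {
    n <- max(1, min(k, length(lib[[aa]]$p)))
    lib[[aa]]$chi <- lib[[aa]]$chi[seq_len(n), , drop = FALSE]
    lib[[aa]]$p <- lib[[aa]]$p[seq_len(n)] / sum(lib[[aa]]$p[seq_len(n)])
  }
  lib
}

# Minimal hand-written PDB text (fixed-width ATOM records).
pdb_atom_line <- function(serial, name, resid, chain, resno, x, y, z,
                          record = "ATOM", elem = substr(name, 1, 1)) {
  sprintf("%-6s%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, resid, chain, resno, x, y, z, 1, 0, elem)
}
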