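# Energy model: reference energies, term shapes, decomposition, hydrogen
# bonds.

test_that("default charged-residue reference energies match the published
           score-function weights", {
  m <- energy_model()
  expect_equal(reference_energy("R", m), -0.98)
  expect_equal(reference_energy("K", m), -0.65)
  expect_equal(reference_energy("D", m), -0.67)
  expect_equal(reference_energy("E", m), -0.81)
  expect_equal(reference_energy("A", m), 0)
  expect_length(m$reference_energies, 20)
  expect_equal(m$hbond_preserve_threshold, -0.5)
  expect_error(energy_model(hbond_preserve_threshold = 0.1), "negative")
})

test_that("residues far beyond every cutoff only contribute reference and
           rotamer terms", {
  a <- make_structure("A")
  b <- transform_structure(make_structure("K", chain = "B"),
                           diag(3), c(50, 0, 0))
  s <- merge_structures(a, b)
  sc <- score_structure(s)
  expect_equal(unname(sc$terms[c("fa_atr", "fa_rep", "fa_sol", "fa_pair",
                                 "hbond_bb_sc", "hbond_sc")]),
               rep(0, 6))
  # total = sum of reference energies + rotamer terms
  lib <- default_rotamers()
  expect_equal(sc$total,
               reference_energy("A") + reference_energy("K") +
                 (-log(max(lib$K$p))))
})

test_that("an isolated residue scores its reference plus rotamer term", {
  s <- make_structure("R")
  sc <- score_structure(s)
  expect_equal(sc$total, -0.98 - log(max(default_rotamers()$R$p)))
})

test_that("per-residue decomposition sums to the total", {
  for (s in list(make_structure("ADKNQAAEKAAQNRA"),
                 make_hbond_motif("NQ_donor_acceptor"),
                 bundle_fixture())) {
    sc <- score_structure(s)
    expect_equal(sum(sc$per_residue$total), sc$total,
                 tolerance = 1e-6)
    expect_equal(sum(sc$terms), sc$total, tolerance = 1e-10)
  }
})

test_that("Lennard-Jones terms equal a naive double-loop recomputation", {
  for (s in list(make_structure("ADKNQAAEK"),
                 make_structure("LVIF", backbone = "ideal_strand"))) {
    sc <- score_structure(s)
    oracle <- oracle_lj_total(s)
    expect_equal(unname(sc$terms[["fa_atr"]]), unname(oracle[["fa_atr"]]),
                 tolerance = 1e-9)
    expect_equal(unname(sc$terms[["fa_rep"]]), unname(oracle[["fa_rep"]]),
                 tolerance = 1e-9)
  }
})

test_that("zeroing one term weight removes exactly that contribution", {
  s <- make_hbond_motif("sidechain_to_backbone_loop")
  full <- score_structure(s)
  for (term in names(full$terms)) {
    w <- rep(1, 8); names(w) <- names(full$terms)
    w[term] <- 0
    part <- score_structure(s, energy_model(weights = w))
    expect_equal(part$total, full$total - full$terms[[term]],
                 tolerance = 1e-9, info = term)
  }
})

test_that("the pair term favors opposite charges and penalizes like
           charges", {
  place_near <- function(aa1, aa2, gap = 4) {
    s1 <- make_structure(aa1)
    s2 <- make_structure(aa2, chain = "B")
    g1 <- superchargeR:::CHARGED_GROUP_ATOMS[[aa1]][1]
    g2 <- superchargeR:::CHARGED_GROUP_ATOMS[[aa2]][1]
    p1 <- unlist(s1$atoms[s1$atoms$atom == g1, c("x", "y", "z")])
    p2 <- unlist(s2$atoms[s2$atoms$atom == g2, c("x", "y", "z")])
    merge_structures(s1, transform_structure(s2, diag(3),
                                             p1 + c(gap, 3, 0) - p2))
  }
  opp <- score_structure(place_near("D", "K"))
  like <- score_structure(place_near("D", "E"))
  expect_lt(opp$terms[["fa_pair"]], 0)
  expect_gt(like$terms[["fa_pair"]], 0)
  # beyond the cutoff the term vanishes
  far <- score_structure(place_near("D", "K", gap = 12))
  expect_equal(unname(far$terms[["fa_pair"]]), 0)
})

test_that("lowering a charged type's reference energy shifts the total by
           count times delta", {
  s <- make_structure("AKAKA")
  base <- score_structure(s)$total
  m <- energy_model(reference_energies = c(R = -0.98, K = -1.65, D = -0.67,
                                           E = -0.81))
  expect_equal(score_structure(s, m)$total, base + 2 * (-1.0),
               tolerance = 1e-9)
})

test_that("geometric terms are rigid-body invariant", {
  s <- make_hbond_motif("NQ_donor_acceptor")
  sc0 <- score_structure(s)
  s2 <- transform_structure(s, random_rotation(11), c(5, -3, 12))
  sc1 <- score_structure(s2)
  expect_equal(sc1$total, sc0$total, tolerance = 1e-9)
  expect_equal(sc1$terms, sc0$terms, tolerance = 1e-9)
})

test_that("the crafted aspartate-to-backbone bond is strong and vanishes on
           mutation", {
  s <- make_hbond_motif("sidechain_to_backbone_loop")
  hb <- detect_sidechain_hbonds(s)
  strong <- hb[hb$strength == "strong", ]
  expect_equal(nrow(strong), 1)
  expect_equal(strong$acceptor_key, "A:12")
  expect_equal(strong$acceptor_atom, "OD1")
  expect_equal(strong$class, "sc_bb")
  expect_lte(strong$energy, -0.5)
  expect_equal(strong$energy, -1, tolerance = 1e-6)  # ideal geometry
  mut <- mutate_residue(s, "A:12", "K")
  hb2 <- detect_sidechain_hbonds(mut)
  expect_equal(nrow(hb2[hb2$strength == "strong", ]), 0)
})

test_that("hydrogen-bond energy follows the distance ramp continuously", {
  # rebuild the loop motif with the donor segment at varying distances
  main <- make_structure("AADAAQN", backbone = "ideal_helix",
                         start_resno = 10L)
  i <- superchargeR:::.resolve_site(main, "A:12")
  a <- main$atoms
  od1 <- unlist(a[a$res_index == i & a$atom == "OD1", c("x", "y", "z")])
  cg <- unlist(a[a$res_index == i & a$atom == "CG", c("x", "y", "z")])
  u <- (od1 - cg) / sqrt(sum((od1 - cg)^2))
  energy_at <- function(d) {
    seg <- make_structure("A", backbone = "extended", start_resno = 1L)
    placed <- superchargeR:::.place_segment(seg, "A:1", "N", "CA",
                                            od1 + d * u, -u)
    hb <- detect_sidechain_hbonds(merge_structures(main, placed))
    hb <- hb[hb$acceptor_atom == "OD1" & hb$donor_key == "A:1", ]
    if (nrow(hb)) hb$energy else 0
  }
  # analytic ramp: linear 2.4 -> 2.8 -> 3.6, zero at the bounds
  expect_equal(energy_at(2.8), -1, tolerance = 1e-9)
  expect_equal(energy_at(2.6), -0.5, tolerance = 1e-9)
  expect_equal(energy_at(3.2), -0.5, tolerance = 1e-9)
  expect_equal(energy_at(3.58), -0.025, tolerance = 1e-9)
  expect_equal(energy_at(2.42), -0.05, tolerance = 1e-9)
  expect_equal(energy_at(5.0), 0)   # beyond the bound: no bond at all
  expect_equal(energy_at(3.65), 0)  # continuity: ~0 just outside
})

test_that("energy config files override weights and reference energies", {
  f <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# comment", "fa_rep = 0.5", "ref_K = -1.2",
               "sol_radius = 6"), f)
  m <- read_energy_config(f)
  expect_equal(unname(m$weights[["fa_rep"]]), 0.5)
  expect_equal(reference_energy("K", m), -1.2)
  expect_equal(m$sol_radius, 6)
  writeLines("nonsense = 1", f)
  expect_error(read_energy_config(f), "unknown config key")
})

test_that("compact scorer agrees with the reference scorer", {
  for (s in list(make_structure("ADKNQAAEKAAQNRA"),
                 make_hbond_motif("helix_cap"),
                 random_fixture(5)))
    expect_equal(compact_total(s), score_structure(s)$total,
                 tolerance = 1e-9)
})
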