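# Energy-guided supercharging: reference-weight control of net charge and
# the target-charge ramp.

small_fix <- function() make_structure("ANQADNA", source_name = "small")

test_that("polarity is inferred from the include flags and mixed signs are
           rejected", {
  expect_error(superchargeR:::.options_polarity(supercharge_options()),
               "at least one")
  expect_error(superchargeR:::.options_polarity(
    supercharge_options(include_lys = TRUE, include_glu = TRUE)), "mix")
  expect_equal(superchargeR:::.options_polarity(
    supercharge_options(include_arg = TRUE)), "positive")
  expect_equal(superchargeR:::.options_polarity(
    supercharge_options(include_asp = TRUE)), "negative")
})

test_that("refweights for non-enabled types are rejected", {
  s <- small_fix()
  expect_error(
    supercharge_with_refweights(s, c(R = -1),
                                supercharge_options(include_lys = TRUE)),
    "not enabled")
})

test_that("a strong reference-energy penalty yields zero charged
           mutations", {
  s <- small_fix()
  res <- supercharge_with_refweights(
    s, c(K = 10), supercharge_options(include_lys = TRUE, seed = 2))
  expect_equal(sum(res$mutations$new_aa == "K"), 0)
  expect_equal(res$net_charge_after, res$net_charge_before)
})

test_that("an extreme reference-energy bonus charges every designable
           site (exhaustive check)", {
  s <- small_fix()
  lib <- trimmed_rotamers(1)
  opts <- supercharge_options(include_lys = TRUE, seed = 4)
  res <- supercharge_with_refweights(s, c(K = -5), opts, rotamers = lib)
  task <- res$task
  designable <- task$key[task$designable]
  seq_out <- residue_sites(res$structure)
  expect_true(all(seq_out$aa[match(designable, seq_out$key)] == "K"))
  # agrees with the exhaustive optimum at the same weights
  model <- energy_model(reference_energies = c(R = -0.98, K = -5,
                                               D = -0.67, E = -0.81))
  ex <- exhaustive_pack(s, task, model, rotamers = lib)
  mc_e <- compact_total(res$structure, model, lib)
  expect_equal(mc_e, ex$energy, tolerance = 1e-6)
})

test_that("with default reference weights the design never worsens the
           model energy", {
  s <- make_structure("ANQADNAEKA")
  opts <- supercharge_options(include_lys = TRUE, seed = 3)
  res <- supercharge_with_refweights(s, options = opts)
  m <- energy_model()
  expect_lte(compact_total(res$structure, m), compact_total(s, m) + 1e-9)
})

test_that("mutations occur only at designable surface sites", {
  s <- make_hbond_motif("sidechain_to_backbone_loop")
  opts <- supercharge_options(include_lys = TRUE, seed = 5)
  res <- supercharge_with_refweights(s, c(K = -3), opts)
  task <- res$task
  expect_true(all(res$mutations$key %in% task$key[task$designable]))
  # the hydrogen-bonded aspartate is preserved
  expect_false("A:12" %in% res$mutations$key)
})

test_that("preserve_correct_charge keeps native charges of the design
           polarity untouched", {
  s <- make_structure("ADEANQKA")
  opts <- supercharge_options(include_glu = TRUE, seed = 6)
  res <- supercharge_with_refweights(s, c(E = -3), opts)
  nat <- residue_sites(s); des <- residue_sites(res$structure)
  de_sites <- nat$key[nat$aa %in% c("D", "E")]
  expect_equal(des$aa[match(de_sites, des$key)],
               nat$aa[match(de_sites, nat$key)])
})

test_that("seed determinism and nstruct selection", {
  s <- small_fix()
  opts <- supercharge_options(include_lys = TRUE, seed = 11)
  r1 <- supercharge_with_refweights(s, options = opts)
  r2 <- supercharge_with_refweights(s, options = opts)
  expect_identical(r1$structure$atoms, r2$structure$atoms)
  opts3 <- supercharge_options(include_lys = TRUE, seed = 11, nstruct = 3)
  r3 <- supercharge_with_refweights(s, c(K = -2), opts3)
  expect_true(r3$seed %in% (11:13))
})

test_that("the ramp reaches a reachable target and records monotone
           weights", {
  s <- small_fix()
  opts <- supercharge_options(include_lys = TRUE, seed = 7)
  res <- supercharge_to_target(s, 3, opts)
  expect_gte(res$net_charge_after, 3)
  expect_equal(res$net_charge_after, net_formal_charge(res$structure))
  expect_true(all(diff(res$ramp$K) <= 0))
  expect_equal(res$final_reference_energies[["K"]],
               res$ramp$K[nrow(res$ramp)])
})

test_that("ramp preconditions and unreachable targets error informatively", {
  s <- small_fix()  # net charge -1
  opts <- supercharge_options(include_lys = TRUE, seed = 8)
  expect_error(supercharge_to_target(s, -1, opts), "more positive")
  neg <- supercharge_options(include_glu = TRUE, seed = 8)
  expect_error(supercharge_to_target(s, -1, neg), "more negative")
  # a fixture whose whole surface is preserved can never move
  all_fixed <- make_structure("GDEG")
  err <- tryCatch(
    suppressWarnings(supercharge_to_target(all_fixed, -4, neg,
                                           max_iter = 2)),
    unreachable_charge_error = identity)
  expect_s3_class(err, "unreachable_charge_error")
  expect_equal(err$best_achievable, -2)
  expect_equal(err$extra$final_reference_energies[["E"]],
               -0.81 - 2 * 0.05)
})

test_that("both included types ramp together preserving their offset", {
  s <- make_structure("ANQADNAVLA")
  opts <- supercharge_options(include_lys = TRUE, include_arg = TRUE,
                              seed = 9)
  res <- tryCatch(supercharge_to_target(s, 3, opts, max_iter = 20),
                  unreachable_charge_error = function(e) e$extra)
  ramp <- if (inherits(res, "supercharge_design")) res$ramp else res$ramp
  expect_equal(ramp$R - ramp$K, rep(-0.98 + 0.65, nrow(ramp)),
               tolerance = 1e-12)
})

test_that("disabling hydrogen-bond preservation enlarges the designable
           set", {
  s <- make_hbond_motif("sidechain_to_backbone_loop")
  surface <- classify_surface(s, "atom_based", 120)
  on_ <- build_design_task(s, surface, "positive", include_lys = TRUE)
  off <- build_design_task(s, surface, "positive", include_lys = TRUE,
                           preserve_hbonded_sidechains = FALSE)
  expect_true(all(on_$designable <= off$designable))
  expect_gt(sum(off$designable), sum(on_$designable))
})

test_that("an all-preserved surface yields an empty-design warning result", {
  s <- make_structure("GDEG")  # G fixed; D/E correct charge in negative mode
  opts <- supercharge_options(include_glu = TRUE, seed = 10)
  expect_warning(res <- supercharge_with_refweights(s, options = opts),
                 "no designable")
  expect_equal(nrow(res$mutations), 0)
  expect_equal(res$net_charge_after, res$net_charge_before)
})
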