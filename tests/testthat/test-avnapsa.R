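# Exposure-ranked supercharging: candidate ordering, target/cutoff
# selection, forced-mutation design.

fake_candidates <- function(native, delta, avn) {
  data.frame(chain = "A", number = seq_along(native), icode = "",
             key = paste0("A:", seq_along(native)), native_aa = native,
             new_aa = ifelse(delta > 0, ifelse(native == "N" |
                                                 native == "Q", "K", "K"),
                             ifelse(native == "N", "D", "E")),
             charge_delta = as.integer(delta), avnapsa = avn,
             stringsAsFactors = FALSE)
}

test_that("structures without polar/charged candidates yield empty lists", {
  s <- make_structure("AVLIG")
  expect_equal(nrow(candidate_list(s, "positive")), 0)
  expect_equal(nrow(candidate_list(s, "negative")), 0)
})

test_that("candidates are sorted by exposure and match a brute-force sort
           oracle", {
  s <- random_fixture(42, n = 14)
  for (pol in c("positive", "negative")) {
    cand <- candidate_list(s, pol)
    native_set <- if (pol == "positive") c("N", "Q", "D", "E")
                  else c("N", "Q", "R", "K")
    ann <- surface_annotation(s)
    oracle <- ann[ann$aa %in% native_set, ]
    oracle <- oracle[order(oracle$avnapsa, oracle$chain, oracle$number), ]
    expect_equal(cand$key, oracle$key, info = pol)
    expect_true(all(diff(cand$avnapsa) >= 0))
  }
})

test_that("candidate polarity rules: D/E/N/Q to K, R/K/Q to E, N to D", {
  s <- make_structure("DENQRKA")
  pos <- candidate_list(s, "positive")
  expect_setequal(pos$native_aa, c("D", "E", "N", "Q"))
  expect_true(all(pos$new_aa == "K"))
  expect_equal(pos$charge_delta[match(c("D", "E", "N", "Q"),
                                      pos$native_aa)], c(2L, 2L, 1L, 1L))
  neg <- candidate_list(s, "negative")
  expect_setequal(neg$native_aa, c("R", "K", "Q", "N"))
  expect_equal(neg$new_aa[match(c("R", "K", "Q", "N"), neg$native_aa)],
               c("E", "E", "E", "D"))
  expect_equal(neg$charge_delta[match(c("R", "K", "Q", "N"),
                                      neg$native_aa)],
               c(-2L, -2L, -1L, -1L))
})

test_that("excluded sites are respected", {
  s <- make_structure("DNQ")
  cand <- candidate_list(s, "positive")
  d_key <- cand$key[cand$native_aa == "D"]
  cand2 <- candidate_list(s, "positive", excluded = d_key)
  expect_false(d_key %in% cand2$key)
  expect_setequal(cand2$native_aa, c("N", "Q"))
})

test_that("target selection takes the shortest prefix and reports the
           achieved charge", {
  cand <- fake_candidates(c("N", "D", "Q"), c(1, 2, 1), c(10, 20, 30))
  chosen <- choose_mutations_to_target(cand, current_charge = -1,
                                       target = 3)
  expect_equal(nrow(chosen), 3)
  expect_equal(attr(chosen, "achieved_charge"), 3)
  # a +/-2 swap crossing the target may overshoot by one
  chosen2 <- choose_mutations_to_target(cand, current_charge = -1,
                                        target = 2)
  expect_equal(nrow(chosen2), 2)
  expect_equal(attr(chosen2, "achieved_charge"), 2)
})

test_that("a no-op target is a usage error, exhaustion an
           unreachable-charge error", {
  cand <- fake_candidates("N", 1, 10)
  expect_error(choose_mutations_to_target(cand, 0, 0), "more positive")
  expect_error(choose_mutations_to_target(cand, 0, -2), "more positive")
  err <- tryCatch(choose_mutations_to_target(cand, 0, 2),
                  unreachable_charge_error = identity)
  expect_s3_class(err, "unreachable_charge_error")
  expect_equal(err$best_achievable, 1)
})

test_that("cutoff selection keeps strictly-below candidates", {
  cand <- fake_candidates(c("N", "N", "N"), c(1, 1, 1), c(100, 149, 151))
  expect_equal(nrow(choose_mutations_by_cutoff(cand, 150)), 2)
  expect_equal(nrow(choose_mutations_by_cutoff(cand, 50)), 0)
  # equals an independent filter of the same table
  expect_equal(choose_mutations_by_cutoff(cand, 150)$key,
               cand$key[cand$avnapsa < 150])
})

test_that("the full protocol reaches the target with exact charge
           bookkeeping", {
  s <- make_structure("ANNQADAA")   # candidates N,N,Q,D ; charge -1
  res <- apply_avnapsa_design(s, "positive", target_charge = 3)
  expect_equal(res$net_charge_before, -1)
  expect_equal(res$net_charge_after,
               res$net_charge_before + sum(res$mutations$charge_delta))
  expect_equal(res$net_charge_after, net_formal_charge(res$structure))
  expect_gte(res$net_charge_after, 3)
  # output sequence differs from input exactly at the mutated sites
  s0 <- residue_sites(s); s1 <- residue_sites(res$structure)
  expect_setequal(s0$key[s0$aa != s1$aa], res$mutations$key)
})

test_that("saturating the candidate list mutates every candidate", {
  s <- make_structure("ANNQADAA")
  cand <- candidate_list(s, "positive")
  max_reach <- net_formal_charge(s) + sum(cand$charge_delta)
  res <- apply_avnapsa_design(s, "positive", target_charge = max_reach)
  expect_equal(nrow(res$mutations), nrow(cand))
  expect_equal(res$net_charge_after, max_reach)
})

test_that("a residue file can veto all candidates", {
  s <- make_structure("ANNA")
  rf <- withr::local_tempfile(fileext = ".resfile")
  writeLines(c("start", "2 A NATRO", "3 A NATRO"), rf)
  expect_error(apply_avnapsa_design(s, "positive", target_charge = 2,
                                    resfile = rf),
               class = "unreachable_charge_error")
})

test_that("a PIKAA line without the replacement type vetoes the site", {
  s <- make_structure("ANNA")
  rf <- withr::local_tempfile(fileext = ".resfile")
  writeLines(c("start", "2 A PIKAA ND"), rf)  # K not allowed at site 2
  res <- apply_avnapsa_design(s, "positive", target_charge = 1,
                              resfile = rf)
  expect_false("A:2" %in% res$mutations$key)
})

test_that("designed sequences never contain new arginine, and aspartate
           only replaces asparagine", {
  for (seed in 1:8) {
    s <- random_fixture(seed, n = 10)
    for (pol in c("positive", "negative")) {
      cand <- candidate_list(s, pol)
      if (!nrow(cand)) next
      reach <- net_formal_charge(s) + sum(cand$charge_delta)
      res <- tryCatch(
        apply_avnapsa_design(s, pol, target_charge = reach),
        unreachable_charge_error = function(e) NULL)
      if (is.null(res)) next
      expect_false(any(res$mutations$new_aa == "R"))
      d_new <- res$mutations[res$mutations$new_aa == "D", ]
      expect_true(all(d_new$native_aa == "N"))
      # mutational economy: each mutation moves 1 or 2 charge units
      mpc <- mutations_per_charge(res)
      expect_gte(mpc, 0.5); expect_lte(mpc, 1.0)
    }
  }
})

test_that("the protocol is deterministic", {
  s <- make_structure("ANNQADAA")
  r1 <- apply_avnapsa_design(s, "positive", target_charge = 3)
  r2 <- apply_avnapsa_design(s, "positive", target_charge = 3)
  expect_identical(r1$structure$atoms, r2$structure$atoms)
  expect_identical(r1$mutations, r2$mutations)
})

test_that("exactly one of target and cutoff must be given", {
  s <- make_structure("ANNA")
  expect_error(apply_avnapsa_design(s, "positive"), "exactly one")
  expect_error(apply_avnapsa_design(s, "positive", target_charge = 2,
                                    cutoff = 100), "exactly one")
})
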