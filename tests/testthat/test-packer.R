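# Design task construction, preservation rules, packing, exhaustive oracle,
# residue files.

test_that("preservation rules assign the documented reasons", {
  s <- make_structure("GDVAKNQ")
  surface <- residue_sites(s)$key
  task <- build_design_task(s, surface, "negative", include_glu = TRUE)
  expect_equal(task$reason[task$aa == "G"], "glyprocys")
  expect_equal(task$reason[task$aa == "D"], "correct_charge")
  expect_true(task$designable[task$aa == "V"])
  expect_true(all(!task$designable | is.na(task$reason)))
  # every residue appears exactly once
  expect_equal(nrow(task), nrow(residue_sites(s)))
})

test_that("allowed types are the native plus the enabled charged types", {
  s <- make_structure("GDVAKNQ")
  surface <- residue_sites(s)$key
  task <- build_design_task(s, surface, "positive",
                            include_lys = TRUE, include_arg = TRUE)
  v <- which(task$aa == "V")
  expect_setequal(task$allowed[[v]], c("V", "K", "R"))
  task_k <- build_design_task(s, surface, "positive", include_lys = TRUE)
  expect_setequal(task_k$allowed[[v]], c("V", "K"))
  # native type is always allowed at designable sites
  for (i in which(task$designable))
    expect_true(task$aa[i] %in% task$allowed[[i]])
})

test_that("strongly hydrogen-bonded side chains are preserved, and the rule
           can be switched off", {
  s <- make_hbond_motif("sidechain_to_backbone_loop")
  surface <- residue_sites(s)$key
  task <- build_design_task(s, surface, "positive", include_lys = TRUE)
  asp <- which(task$key == "A:12")
  expect_false(task$designable[asp])
  expect_equal(task$reason[asp], "hbonded_sidechain")
  task_off <- build_design_task(s, surface, "positive", include_lys = TRUE,
                                preserve_hbonded_sidechains = FALSE)
  expect_true(task_off$designable[asp])
  expect_true(all(task$designable <= task_off$designable))
})

test_that("not-surface and resfile exclusions are recorded", {
  s <- make_structure("ANQAK")
  surface <- c("A:2", "A:3")
  rf <- withr::local_tempfile(fileext = ".resfile")
  writeLines(c("start", "2 A NATRO"), rf)
  task <- build_design_task(s, surface, "positive", include_lys = TRUE,
                            resfile = rf)
  expect_equal(task$reason[task$key == "A:1"], "not_surface")
  expect_equal(task$reason[task$key == "A:2"], "resfile_excluded")
  expect_true(task$designable[task$key == "A:3"])
  writeLines(c("start", "99 A NATRO"), rf)
  expect_error(build_design_task(s, surface, "positive", include_lys = TRUE,
                                 resfile = rf), "absent")
})

test_that("a task with zero designable sites packs to the input", {
  s <- make_structure("GGGG")
  task <- build_design_task(s, residue_sites(s)$key, "positive",
                            include_lys = TRUE)
  expect_false(any(task$designable))
  out <- pack_rotamers(s, task, seed = 7)
  expect_identical(out$structure$atoms, s$atoms)
  expect_equal(out$energy, score_structure(s)$total, tolerance = 1e-9)
  ex <- exhaustive_pack(s, task)
  expect_equal(ex$energy, out$energy, tolerance = 1e-9)
})

test_that("packing is seed-deterministic and never touches fixed sites", {
  s <- random_fixture(21)
  surface <- residue_sites(s)$key
  task <- build_design_task(s, surface, "positive", include_lys = TRUE)
  r1 <- pack_rotamers(s, task, seed = 5)
  r2 <- pack_rotamers(s, task, seed = 5)
  expect_identical(r1$structure$atoms, r2$structure$atoms)
  expect_equal(r1$energy, r2$energy)
  fixed <- which(!task$designable)
  for (i in fixed) {
    a0 <- s$atoms[s$atoms$res_index == i, ]
    a1 <- r1$structure$atoms[r1$structure$atoms$res_index == i, ]
    expect_identical(a1$atom, a0$atom)
    expect_equal(unname(as.matrix(a1[, c("x", "y", "z")])),
                 unname(as.matrix(a0[, c("x", "y", "z")])))
  }
})

test_that("packing never worsens the energy relative to the native
           assignment", {
  for (seed in c(3, 9)) {
    s <- random_fixture(seed)
    task <- build_design_task(s, residue_sites(s)$key, "positive",
                              include_lys = TRUE)
    out <- pack_rotamers(s, task, seed = seed)
    expect_lte(out$energy, score_structure(s)$total + 1e-9)
  }
})

test_that("exhaustive enumeration refuses oversized search spaces", {
  s <- make_structure("NQNQNQNQNQ")
  task <- build_design_task(s, residue_sites(s)$key, "positive",
                            include_lys = TRUE)
  expect_error(exhaustive_pack(s, task, max_states = 10), "too large")
})

test_that("annealed packing attains the exhaustive optimum on small tasks", {
  lib <- trimmed_rotamers(1)
  hits <- 0; n_tasks <- 10
  for (seed in seq_len(n_tasks)) {
    s <- random_fixture(seed + 100, n = 8)
    task <- build_design_task(s, residue_sites(s)$key, "positive",
                              include_lys = TRUE)
    keep <- which(task$designable)
    if (length(keep) > 3) {
      task$designable[keep[-(1:3)]] <- FALSE
      task$reason[keep[-(1:3)]] <- "resfile_excluded"
    }
    mc <- pack_rotamers(s, task, seed = seed, rotamers = lib)
    ex <- exhaustive_pack(s, task, rotamers = lib)
    expect_gte(mc$energy, ex$energy - 1e-9)
    if (abs(mc$energy - ex$energy) < 1e-6) hits <- hits + 1
  }
  expect_gte(hits, n_tasks - 1)
})

test_that("a sterically impossible rotamer is never chosen over a clean
           one", {
  # mutate into a crowded pocket: exhaustive and annealed agree, and the
  # chosen rotamer carries less repulsion than the worst alternative
  s <- bundle_fixture()
  ann <- surface_annotation(s)
  buried <- ann$key[which.max(ann$neighbor_count)]
  task <- build_design_task(s, buried, "positive", include_lys = TRUE,
                            design_chain = substr(buried, 1, 1))
  if (any(task$designable)) {
    mc <- pack_rotamers(s, task, seed = 2)
    ex <- exhaustive_pack(s, task)
    expect_equal(mc$energy, ex$energy, tolerance = 1e-6)
  } else succeed("buried site preserved; nothing to pack")
})

test_that("residue files round-trip and reproduce the designable set", {
  s <- make_structure("GDVAKNQ")
  surface <- residue_sites(s)$key
  task <- build_design_task(s, surface, "positive", include_lys = TRUE)
  rf <- withr::local_tempfile(fileext = ".resfile")
  write_resfile(task, rf)
  parsed <- read_resfile(rf)
  expect_equal(nrow(parsed), nrow(task))
  task2 <- build_design_task(s, surface, "positive", include_lys = TRUE,
                             resfile = rf)
  expect_equal(task2$designable, task$designable)
})

test_that("malformed residue files are rejected", {
  rf <- withr::local_tempfile(fileext = ".resfile")
  writeLines(c("2 A NATRO"), rf)
  expect_error(read_resfile(rf), "start")
  writeLines(c("start", "2 A FROBNICATE"), rf)
  expect_error(read_resfile(rf), "malformed")
  writeLines(c("start", "2 A PIKAA"), rf)
  expect_error(read_resfile(rf), "PIKAA")
})
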