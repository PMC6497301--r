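test_that("z-score discretization applies the core/nonexpressed thresholds", {
  z <- c(a = 6, b = -1, c = 2, d = 5, e = 0)
  st <- discretize_expression(z)
  expect_identical(unname(st[c("a", "b", "c")]),
                   c("core", "nonexpressed", "moderate"))
  # boundary values are moderate
  expect_identical(unname(st[c("d", "e")]), c("moderate", "moderate"))
  expect_warning(discretize_expression(c(a = NaN, b = 6)), "non-finite")
})

test_that("core determination maps gene states through GPRs", {
  m <- two_path_model()   # P1: gmod, P2: glow
  st <- c(gmod = "core", glow = "nonexpressed")
  spec <- core_from_states(m, st)
  expect_identical(spec$core, "P1")
  expect_identical(spec$forced, "BIOMASS")
  # AND requires both genes, OR either
  S <- rbind(A = c(-1, -1, -1, 0), B = c(0, 1, 1, -1))
  colnames(S) <- c("EX_a", "R_and", "R_or", "BIOMASS")
  m2 <- metabolic_model(S, lb = c(-10, 0, 0, 0), ub = rep(1000, 4),
                        gpr = c("", "(x and y)", "(x or y)", ""),
                        objective_id = "BIOMASS")
  sp2 <- core_from_states(m2, c(x = "core", y = "moderate"))
  expect_identical(sp2$core, "R_or")
  expect_identical(sp2$non_penalized, "R_and")
  # reactions without GPR are never expression-core
  expect_false("EX_a" %in% sp2$core)
})

test_that("FASTCORE completes a mid-chain core to the whole chain", {
  m <- example_chain_model()
  cm <- fastcore(m, core = "T1")
  expect_setequal(cm$reaction_ids, c("EX_a", "T1", "BIOMASS"))
  # empty core, no forced set: empty model
  expect_length(fastcore(m, core_spec())$reaction_ids, 0)
  # core = everything on a consistent model: identity
  expect_setequal(fastcore(m, m$reaction_ids)$reaction_ids, m$reaction_ids)
  # a blocked core reaction is named in the error
  mb <- random_fixture(21, n_blocked = 1)
  expect_error(fastcore(mb, "D_1"), "D_1")
})

test_that("FASTCORE output is minimal on small fixtures", {
  for (seed in 17:20) {
    m <- random_fixture(seed, n_pathways = 2, pathway_length = 2)
    cons <- setdiff(m$reaction_ids, fastcc(m)$blocked)
    core <- intersect(c("T0", "R_1_1"), cons)
    cm <- fastcore(m, core)
    expect_true(all(core %in% cm$reaction_ids))
    expect_true(submodel_consistent(m, cm$reaction_ids))
    expect_equal(length(cm$reaction_ids),
                 min_consistent_superset(m, core),
                 info = paste("seed", seed))
  }
})

test_that("the functionality-preserving variant always keeps biomass", {
  # biomass requires a nonexpressed reaction: plain FASTCORE on the core
  # alone may exclude it, the modified extractor must include it
  m <- two_path_model()
  st <- c(gmod = "nonexpressed", glow = "nonexpressed")
  # an empty expression core warns but does not error
  expect_warning(
    cm <- fastcormics_modified(m, core = character(0), states = st),
    "empty core")
  expect_true("BIOMASS" %in% cm$reaction_ids)
  expect_gt(fba(cm)$objective_value, 0)
  # all genes core: the consistent parent comes back
  st2 <- c(gmod = "core", glow = "core")
  spec <- core_from_states(m, st2)
  cm2 <- fastcormics_modified(m, core = spec)
  expect_setequal(cm2$reaction_ids, m$reaction_ids)
})

test_that("non-penalized routes are preferred over penalized ones", {
  m <- two_path_model()
  spec <- core_spec(core = character(0),
                    non_penalized = "P1", forced = "BIOMASS")
  cm <- fastcore(m, spec)
  expect_true("P1" %in% cm$reaction_ids)
  expect_false("P2" %in% cm$reaction_ids)
})

test_that("extraction is deterministic and records provenance", {
  m <- random_fixture(22, n_pathways = 2)
  cons <- setdiff(m$reaction_ids, fastcc(m)$blocked)
  core <- intersect("T0", cons)
  a <- fastcore(m, core)
  b <- fastcore(m, core)
  expect_identical(a$reaction_ids, b$reaction_ids)
  expect_identical(a$method, "fastcore")
  expect_identical(a$parent_id, m$id)
  p <- withr::local_tempfile(fileext = ".json")
  write_context_model(a, p)
  prov <- jsonlite::read_json(paste0(p, ".provenance.json"))
  expect_identical(prov$parent, m$id)
  expect_identical(prov$method, "fastcore")
})
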