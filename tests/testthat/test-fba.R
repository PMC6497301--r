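test_that("FBA solves the chain toy and reports failure modes", {
  m <- example_chain_model()
  sol <- fba(m)
  expect_identical(sol$status, "optimal")
  expect_equal(sol$objective_value, 10)
  expect_equal(unname(sol$fluxes), c(-10, 10, 10))
  # steady state and bounds hold tightly
  expect_lt(max(abs(m$S %*% sol$fluxes)), 1e-9)
  expect_true(all(sol$fluxes >= m$lb - 1e-9 & sol$fluxes <= m$ub + 1e-9))
  # no input, no growth
  m0 <- m; m0$lb["EX_a"] <- 0
  expect_equal(fba(m0)$objective_value, 0)
  expect_error(fba(m, objective = "nope"), "not in the model")
})

test_that("pFBA zeroes futile cycles and keeps the optimum", {
  m <- futile_cycle_model()
  plain <- fba(m)
  pars <- pfba(m)
  expect_equal(pars$objective_value, plain$objective_value,
               tolerance = 1e-6)
  expect_lt(abs(pars$fluxes[["C1"]]), 1e-6)
  expect_lt(abs(pars$fluxes[["C2"]]), 1e-6)
  # unique-optimum network: pfba equals fba
  chain <- example_chain_model()
  expect_equal(pfba(chain)$fluxes, fba(chain)$fluxes, tolerance = 1e-7)
  # infeasibility propagates (force lb > attainable flux)
  bad <- chain
  bad$lb["BIOMASS"] <- 500
  expect_false(pfba(bad)$status == "optimal")
})

test_that("FVA brackets fluxes and finds blocked reactions", {
  m <- example_chain_model()
  rng <- fva(m, objective_fraction = 0)
  expect_equal(rng$min[rng$reaction_id == "EX_a"], -10)
  expect_equal(rng$max[rng$reaction_id == "EX_a"], 0)
  # fraction 1 pins the objective to its optimum
  rng1 <- fva(m, "BIOMASS", objective_fraction = 1)
  expect_equal(rng1$min, 10, tolerance = 1e-6)
  expect_equal(rng1$max, 10, tolerance = 1e-6)
  # planted dead end has range [0, 0]
  mb <- random_fixture(7, n_blocked = 1)
  rngb <- fva(mb, objective_fraction = 0)
  expect_equal(unlist(rngb[rngb$reaction_id == "D_1", c("min", "max")]),
               c(min = 0, max = 0))
})

test_that("gene deletions follow GPR semantics", {
  m <- example_chain_model()     # g1 on the only transport step
  expect_equal(single_gene_deletion(m, "g1"), 0)
  iso <- two_path_model()        # two OR-routes with separate genes
  expect_equal(single_gene_deletion(iso, "gmod"), 10)
  expect_error(single_gene_deletion(m, "nope"), "unknown gene")
  expect_setequal(essential_genes(m), "g1")
  expect_length(essential_genes(iso), 0)
})

test_that("essentiality is monotone in the threshold and defaults to 1%", {
  expect_identical(formals(essential_genes)$threshold, 0.01)
  m <- random_fixture(8, n_pathways = 2)
  e_strict <- essential_genes(m, threshold = 0.5)
  e_loose <- essential_genes(m, threshold = 0.001)
  expect_true(all(e_strict %in% e_loose))
  m0 <- m; m0$lb["EX_sub"] <- 0
  expect_error(essential_genes(m0), "positive")
})

test_that("FBA optima agree with an external constraint-based solver", {
  # cobrapy + GLPK as an independent oracle on generated fixtures
  oracle <- system.file("oracle", "cobra_fba.py", package = "trfbacore")
  py <- Sys.which("python")
  for (seed in c(1, 9)) {
    m <- random_fixture(seed, n_blocked = 1)
    path <- withr::local_tempfile(fileext = ".json")
    write_model(m, path)
    out <- system2(py, c(oracle, path), stdout = TRUE)
    expect_identical(out[1], "optimal")
    expect_equal(fba(m)$objective_value, as.numeric(out[2]),
                 tolerance = 1e-6)
  }
})
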