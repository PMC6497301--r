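test_that("model construction validates its invariants", {
  m <- example_chain_model()
  expect_s3_class(m, "metabolic_model")
  expect_identical(m$exchange_ids, c("EX_a", "BIOMASS"))
  expect_silent(validate_model(m))
  # GPR naming an unknown gene
  expect_error(
    metabolic_model(m$S, m$lb, m$ub, gpr = c("", "gX", ""),
                    gene_ids = "g1", objective_id = "BIOMASS"),
    "unknown gene")
  expect_error(
    metabolic_model(m$S, m$lb, m$ub, objective_id = "nope"),
    "not in the model")
  expect_error(
    metabolic_model(m$S, lb = c(5, 0, 0), ub = c(0, 1, 1),
                    objective_id = "BIOMASS"),
    "lower bound exceeds")
})

test_that("JSON model round-trip is lossless", {
  for (seed in 1:4) {
    m <- random_fixture(seed, n_blocked = seed %% 2)
    path <- withr::local_tempfile(fileext = ".json")
    write_model(m, path)
    m2 <- read_model(path)
    for (f in c("S", "lb", "ub", "gpr", "objective_id", "gene_ids",
                "reaction_ids", "metabolite_ids", "exchange_ids"))
      expect_equal(m2[[f]], m[[f]], info = paste(seed, f))
  }
})

test_that("SBML round-trip preserves the model semantically", {
  m <- random_fixture(5)
  path <- withr::local_tempfile(fileext = ".xml")
  write_model(m, path, dialect = "sbml")
  m2 <- read_model(path)
  expect_equal(unname(m2$S), unname(m$S))
  expect_equal(unname(m2$lb), unname(m$lb))
  expect_equal(unname(m2$ub), unname(m$ub))
  expect_identical(m2$objective_id, m$objective_id)
  expect_equal(fba(m2)$objective_value, fba(m)$objective_value)
  # GPR trees equivalent (whitespace/parenthesization may differ)
  for (k in seq_along(m$reaction_ids)) {
    genes <- gpr_genes(m$gpr_trees[[k]])
    expect_setequal(gpr_genes(m2$gpr_trees[[k]]), genes)
    for (g in genes)
      expect_identical(eval_gpr(m2$gpr_trees[[k]], knocked_out = g),
                       eval_gpr(m$gpr_trees[[k]], knocked_out = g))
  }
})

test_that("read_model reports malformed input", {
  p <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(metabolites = list("A")), p, auto_unbox = TRUE)
  expect_error(read_model(p), "missing element")
  expect_error(read_model("/nonexistent/m.json"), "not found")
})

test_that("apply_medium sets uptake bounds under the sign convention", {
  m <- example_chain_model()
  med0 <- medium_spec(c(EX_a = 0))
  expect_equal(apply_medium(m, med0)$lb[["EX_a"]], 0)
  med10 <- medium_spec(c(EX_a = 10))
  m10 <- apply_medium(m, med10)
  expect_equal(m10$lb[["EX_a"]], -10)
  expect_equal(m10$ub[["EX_a"]], m$ub[["EX_a"]])
  # idempotent
  expect_equal(apply_medium(m10, med10), m10)
  # input not mutated
  expect_equal(m$lb[["EX_a"]], -10)
  expect_error(apply_medium(m, medium_spec(c(T1 = 5))), "not exchange")
  expect_error(medium_spec(c(EX_a = -1)), ">= 0")
})

test_that("cell-specific media are filled from the general medium", {
  gen <- medium_spec(c(EX_a = 10, EX_b = 5))
  spec <- medium_spec(c(EX_a = 2), cell_specific = TRUE)
  filled <- fill_medium(spec, gen)
  expect_equal(filled$uptake, c(EX_a = 2, EX_b = 5))
  expect_true(filled$cell_specific)
})

test_that("uptake-rate conversion implements the volume scaling", {
  expect_equal(convert_uptake_rate(0, 600), 0)
  expect_equal(convert_uptake_rate(100, 430), 1.0)
  # linear in the rate, homogeneous of degree -1 in the volume
  expect_equal(convert_uptake_rate(50, 430), 0.5)
  expect_equal(convert_uptake_rate(100, 860), 0.5)
  # the coefficient defaults to 4.3 mL/gDW but is configurable
  expect_equal(convert_uptake_rate(100, 430, coefficient = 8.6), 2)
  expect_error(convert_uptake_rate(1, 0), "> 0")
})

test_that("doubling-time conversion is ln(2)/dt", {
  expect_equal(doubling_time_to_growth(log(2)), 1.0)
  expect_equal(doubling_time_to_growth(24), log(2) / 24)
  expect_error(doubling_time_to_growth(0), "> 0")
})

test_that("expression and medium TSVs round-trip", {
  fx <- make_fixture(fixture_spec(seed = 6, n_samples = 3))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_expression_tsv(fx$expression, p)
  back <- read_expression_tsv(p)
  expect_equal(back, fx$expression, ignore_attr = TRUE,
               tolerance = 1e-12)
  pm <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("exchange_id\tuptake", "EX_a\t7.5"), pm)
  med <- read_medium_tsv(pm)
  expect_equal(med$uptake, c(EX_a = 7.5))
})
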