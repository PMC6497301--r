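test_that("fixture generation is a pure function of its spec", {
  spec <- fixture_spec(seed = 60, n_samples = 4, n_blocked = 2)
  a <- make_fixture(spec)
  b <- make_fixture(spec)
  expect_identical(a$model$S, b$model$S)
  expect_identical(a$model$gpr, b$model$gpr)
  expect_identical(a$expression, b$expression)
  expect_identical(a$phenotype$growth, b$phenotype$growth)
})

test_that("planted structure is recoverable by the pipeline stages", {
  spec <- fixture_spec(seed = 61, n_samples = 4, n_blocked = 3)
  m <- make_toy_model(spec)
  # parent model is feasible before constraints
  expect_gt(fba(m)$objective_value, 0)
  # planted dead ends are exactly the blocked set
  expect_setequal(fastcc(m)$blocked, attr(m, "blocked_truth"))
  # planted bottleneck gene is essential
  expect_true(attr(m, "bottleneck_gene") %in% essential_genes(m))
})

test_that("expression panels hit the target inter-sample correlation", {
  spec <- fixture_spec(seed = 62, n_samples = 8, cor_target = 0.9)
  m <- make_toy_model(spec)
  E <- make_expression_panel(m, spec)
  expect_true(all(E >= 0))
  ach <- attr(E, "achieved_cor")
  expect_gte(ach, 0.85); expect_lte(ach, 0.95)
  # single-sample panels are trivially valid
  E1 <- make_expression_panel(m, fixture_spec(seed = 62, n_samples = 1))
  expect_identical(ncol(E1), 1L)
})

test_that("phenotypes follow the planted ground truth", {
  spec <- fixture_spec(seed = 63, n_samples = 6)
  fx <- make_fixture(spec)
  ph <- fx$phenotype
  # growth increases with the planted C* (monotone constraint relaxation)
  o <- order(ph$c_star)
  expect_false(is.unsorted(ph$growth[o]))
  # exchange rates re-convert to the planted growth-linked uptake flux
  back <- convert_uptake_rate(ph$exchange_rates["EX_sub", ],
                              ph$cell_volume)
  expect_equal(unname(back), unname(ph$growth), tolerance = 1e-9)
  # zero essentiality noise: the phenotype set equals the deletion set
  expect_setequal(ph$essential, essential_genes(fx$model))
  # drug targets come from the biomass path with positive IC50s; when flux
  # capacities differ the IC50 order is inverted
  expect_true(all(ph$drugs$ic50 > 0))
  fvv <- vapply(ph$drugs$target_reaction, function(r)
    fba(fx$model, r, "max")$objective_value, numeric(1))
  if (stats::sd(fvv) > 0)
    expect_lte(stats::cor(fvv, ph$drugs$ic50, method = "spearman"), 0)
})

test_that("fixture sets serialize to plain-text files", {
  fx <- make_fixture(fixture_spec(seed = 64, n_samples = 3))
  dir <- withr::local_tempdir()
  write_fixture(fx, dir)
  expect_true(all(file.exists(file.path(dir,
    c("model.json", "model.xml", "expression.tsv", "growth.tsv",
      "exchange_rates.tsv", "essential_genes.txt", "drugs.tsv")))))
  m2 <- read_model(file.path(dir, "model.json"))
  expect_equal(m2$S, fx$model$S)
})
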