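test_that("expression constraints cap gene-associated flux sums", {
  # one gene over two irreversible reactions: one pooled constraint row
  S <- rbind(A = c(-1, -1, -1, 0), B = c(0, 1, 1, -1))
  colnames(S) <- c("EX_a", "P1", "P2", "BIOMASS")
  m <- metabolic_model(S, lb = c(-10, 0, 0, 0), ub = rep(1000, 4),
                       gpr = c("", "g1", "g1", ""), objective_id = "BIOMASS")
  tm <- build_trfba_model(m, c(g1 = 2), C = 3)
  expect_equal(nrow(tm$G), 1)
  expect_setequal(colnames(tm$G)[tm$G[1, ] > 0], c("P1", "P2"))
  # v1 + v2 <= C*E = 6 binds the growth
  expect_equal(trfba_growth(tm), 6, tolerance = 1e-8)
  # C = 0 shuts every gene-associated reaction; biomass needs one
  expect_equal(trfba_growth(tm, C = 0), 0, tolerance = 1e-10)
  # huge C: unconstrained optimum
  expect_equal(trfba_growth(tm, C = 1e7), 10, tolerance = 1e-6)
  expect_error(build_trfba_model(m, c(g1 = -1)), ">= 0")
  expect_error(build_trfba_model(m, c(zz = 1)), "no model gene")
})

test_that("C_brk is the point where constraints stop limiting growth", {
  m <- example_chain_model()           # bottleneck gene g1, uptake 10
  cb <- find_c_brk(m, c(g1 = 1))
  expect_equal(cb$C_brk, 10, tolerance = 1e-2)
  expect_equal(cb$G_max, 10)
  # doubling the expression halves C_brk
  cb2 <- find_c_brk(m, c(g1 = 2))
  expect_equal(cb2$C_brk, cb$C_brk / 2, tolerance = 1e-2)
  expect_error(find_c_brk(m, c(g1 = 1), tol = 0), "> 0")
})

test_that("the C sweep is monotone with the expected endpoints", {
  m <- random_fixture(30, n_pathways = 2, frac_gene_associated = 1)
  set.seed(30)
  expr <- stats::setNames(stats::runif(length(m$gene_ids), 5, 50),
                          m$gene_ids)
  sw <- sweep_c(m, expr, n_steps = 60)
  expect_equal(sw$growth[1], 0, tolerance = 1e-9)   # fully gene-associated
  expect_equal(sw$growth[60], sw$G_max, tolerance = 1e-6)
  expect_true(all(diff(sw$growth) >= -1e-6))
  # flux columns are steady-state feasible
  res <- apply(sw$V, 2, function(v) max(abs(m$S %*% v)))
  expect_lt(max(res), 1e-7)
})

test_that("growth-correlated sets are stable across grid sizes", {
  m <- random_fixture(31, n_pathways = 2, frac_gene_associated = 1)
  set.seed(31)
  expr <- stats::setNames(stats::runif(length(m$gene_ids), 5, 50),
                          m$gene_ids)
  cb <- find_c_brk(m, expr)
  sets <- lapply(c(60, 120), function(ns) {
    sw <- sweep_c(m, expr, n_steps = ns, slacks = FALSE, c_brk = cb)
    growth_correlated_reactions(sw)$reaction_id
  })
  expect_gte(jaccard(sets[[1]], sets[[2]]), 0.9)
})

test_that("growth correlation selects fluxes tracking growth", {
  m <- example_chain_model()
  sw <- sweep_c(m, c(g1 = 1), n_steps = 25, slacks = FALSE)
  gc <- growth_correlated_reactions(sw)
  # T1 tracks growth exactly; EX_a is its mirror and enters sign-agnostic
  expect_true(all(c("T1", "EX_a", "BIOMASS") %in% gc$reaction_id))
  expect_equal(abs(gc$rho), rep(1, nrow(gc)))
  # constant-flux reactions are excluded; a flat growth signal is an error
  fake <- structure(list(
    c_grid = seq(0, 1, length.out = 12),
    V = matrix(c(seq_len(12), rep(2, 12)), 2, 12, byrow = TRUE,
               dimnames = list(c("up", "flat"), NULL)),
    growth = seq(0.1, 1.2, length.out = 12),
    status = rep("optimal", 12)), class = "c_sweep")
  sel <- growth_correlated_reactions(fake)
  expect_identical(sel$reaction_id, "up")
  fake$growth <- rep(1, 12)
  expect_error(growth_correlated_reactions(fake), "constant")
})

test_that("slack minimization matches hand-computed QP solutions", {
  m <- example_chain_model()
  m$ub["T1"] <- 5
  q <- qp_slack_minimize(m, C = 8, expr = c(g1 = 1))
  expect_equal(unname(q$alpha), 3, tolerance = 1e-7)
  expect_equal(q$objective, 9, tolerance = 1e-6)
  # perfectly attainable level: zero slack
  q0 <- qp_slack_minimize(m, C = 4, expr = c(g1 = 1))
  expect_equal(unname(q0$alpha), 0, tolerance = 1e-7)
  # C = 0 forces constrained fluxes to zero with zero slack
  qz <- qp_slack_minimize(m, C = 0, expr = c(g1 = 1))
  expect_equal(unname(qz$alpha), 0, tolerance = 1e-9)
})

test_that("slack QP objective matches the dense active-set oracle", {
  for (seed in 32:35) {
    m <- random_fixture(seed, n_pathways = 1, pathway_length = 2,
                        frac_gene_associated = 1, reversible_fraction = 0)
    set.seed(seed)
    expr <- stats::setNames(stats::runif(length(m$gene_ids), 2, 8),
                            m$gene_ids)
    tm <- build_trfba_model(m, expr, C = 0.05)
    q <- qp_slack_minimize(tm)
    sp <- tm$split
    oracle <- qp_brute(tm$G, 0.05 * tm$E, sp$S,
                       rep(0, ncol(sp$S)), sp$ub)
    expect_equal(q$objective, oracle,
                 tolerance = 1e-6 * max(1, oracle),
                 info = paste("seed", seed))
  }
})

test_that("near-zero slack counting uses the 1e-6 default", {
  expect_identical(formals(count_small_slacks)$threshold, 1e-6)
  expect_equal(count_small_slacks(c(0, 1e-7, 1e-3)), 2)
  expect_equal(count_small_slacks(rep(0, 5)), 5)
  expect_error(count_small_slacks(c(1, NA)), "finite")
})

test_that("change-point detection recovers planted steps", {
  d <- detect_c_corr(c(0, 0, 0, 6, 6, 6), 0:5)
  expect_equal(d$index, 4)
  expect_equal(d$C_corr, 3)
  expect_error(detect_c_corr(rep(2, 8), 1:8), "no change")
  # two planted steps: the first is reported, the last via the flag
  x <- c(0, 0, 0, 5, 5, 5, 9, 9, 9)
  d2 <- detect_c_corr(x, 1:9)
  expect_equal(d2$index, 4)
  expect_equal(detect_c_corr(x, 1:9, which = "last")$index, 7)
  expect_setequal(d2$breakpoints, c(4, 7))
  # noisy step at signal-to-noise 5: recovered within one grid index
  set.seed(40)
  for (rep in 1:5) {
    y <- c(rep(0, 10), rep(5, 10)) + stats::rnorm(20, 0, 1)
    dd <- detect_c_corr(y, 1:20)
    expect_lte(abs(dd$index - 11), 1)
  }
})

test_that("C_opt is the stated linear function of measured growth", {
  expect_equal(compute_c_opt(10, 2, 1), 5)
  expect_equal(compute_c_opt(7, 3, 3), 7)        # G_measured = G_max
  expect_equal(compute_c_opt(10, 2, 0), 0)
  expect_error(compute_c_opt(10, 0, 1), "> 0")
})

test_that("the pipeline recovers the planted pathway and is deterministic", {
  fx <- make_fixture(fixture_spec(seed = 41, n_samples = 3))
  fit <- trfba_core(fx$model, fx$expression[, 2],
                    growth_measured = unname(fx$phenotype$growth[2]),
                    n_steps = 40)
  # the planted bottleneck path is in the extracted model and it grows
  expect_true(all(c("EX_sub", "T0", "BIOMASS") %in%
                    fit$context$reaction_ids))
  expect_gt(fit$growth_predicted, 0)
  expect_equal(fit$growth_predicted, unname(fx$phenotype$growth[2]),
               tolerance = 0.05)
  # determinism
  fit2 <- trfba_core(fx$model, fx$expression[, 2],
                     growth_measured = unname(fx$phenotype$growth[2]),
                     n_steps = 40)
  expect_identical(fit$context$reaction_ids, fit2$context$reaction_ids)
  expect_identical(coef(fit), coef(fit2))
  # accessors
  expect_named(coef(fit), c("C_brk", "G_max", "C_corr", "C_opt", "C_used"))
  expect_output(print(fit), "C_opt")
  s <- summary(fit)
  expect_s3_class(s, "summary.trfba_core")
  expect_equal(predict(fit), fit$growth_predicted, tolerance = 1e-8)
})
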