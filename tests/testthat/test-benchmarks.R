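test_that("relative growth error follows its closed form", {
  expect_equal(growth_error(1, 1), 0)
  expect_equal(growth_error(0.5, 0.25), 0.5)
  expect_equal(growth_error(0.5, 0.75), 0.5)
  expect_error(growth_error(0, 1), "> 0")
})

test_that("exchange-rate prediction holds growth at its fraction", {
  m <- example_chain_model()
  # biomass >= 90% of 10 forces uptake of at least 9: maximal (least
  # negative) exchange flux is -9
  expect_equal(predict_exchange_rate(m, "EX_a", 0.9), -9, tolerance = 1e-6)
  expect_equal(predict_exchange_rate(m, "EX_a", 1), -10, tolerance = 1e-6)
  # closed uptake under test predicts 0
  m0 <- m; m0$lb["EX_a"] <- 0
  expect_error(predict_exchange_rate(m0, "EX_a"), "must grow")
  expect_equal(predict_exchange_rate(m0, "EX_a", reset_bound = 10), -9,
               tolerance = 1e-6)
  expect_error(predict_exchange_rate(m, "T1"), "not an exchange")
})

test_that("Spearman correlation matches brute-force ranks with BH batching", {
  expect_equal(correlate(1:5, c(2, 4, 6, 8, 10))$rho, 1)
  expect_equal(correlate(1:5, 5:1)$rho, -1)
  # hand-ranked 5-point example with a tie
  x <- c(1.2, 0.5, 3.1, 2.2, 2.2)
  y <- c(10, 2, 30, 15, 40)
  rho_hand <- stats::cor(rank(x), rank(y))   # midranks, Pearson on ranks
  expect_equal(correlate(x, y)$rho, rho_hand)
  expect_error(correlate(1:2, 1:2), "at least 3")
  batch <- correlate(cbind(a = 1:5, b = c(1, 3, 2, 5, 4)),
                     cbind(a = 2:6, b = 5:1))
  expect_named(batch, c("rho", "p", "q"))
  expect_equal(batch$q, p.adjust(batch$p, "BH"))
})

test_that("drug response is the target flux at half-maximal growth", {
  m <- example_chain_model()
  # chain: biomass fixed at 5 forces T1 = 5 exactly
  expect_equal(simulate_drug_response(m, "T1"), 5, tolerance = 1e-6)
  expect_identical(formals(simulate_drug_response)$biomass_fraction, 0.5)
  # absent target: non-predictable, not an error
  expect_true(is.na(simulate_drug_response(m, "absent_rxn")))
})

test_that("hypergeometric tails match exact combinatorics", {
  # C(5,4) C(5,0) / C(10,4) = 5/210
  expect_equal(hypergeom_enrichment(4, 4, 5, 10), 5 / 210)
  expect_equal(hypergeom_enrichment(0, 0, 7, 20), 1)
  # left + right of the same cell overlap in exactly the point mass
  k <- 3; n <- 8; K <- 10; N <- 25
  pt <- stats::dhyper(k, K, N - K, n)
  expect_equal(hypergeom_enrichment(k, n, K, N, "right") +
                 hypergeom_enrichment(k, n, K, N, "left"), 1 + pt)
  expect_error(hypergeom_enrichment(5, 4, 5, 10), "inconsistent")
  # sweep against the log-combinatorics oracle
  set.seed(50)
  for (rep in 1:40) {
    N <- sample(5:60, 1); K <- sample(0:N, 1); n <- sample(0:N, 1)
    k <- sample(max(0, n + K - N):min(n, K), 1)
    expect_equal(hypergeom_enrichment(k, n, K, N, "right"),
                 hyper_tail_brute(k, n, K, N, "right"), tolerance = 1e-12)
    expect_equal(hypergeom_enrichment(k, n, K, N, "left"),
                 hyper_tail_brute(k, n, K, N, "left"), tolerance = 1e-12)
  }
})

test_that("fold enrichment divides selection and universe fractions", {
  genes <- paste0("g", 1:10)
  ann <- c("g1", "g2")
  expect_equal(og_ts_fold_enrichment(genes, ann, genes)$fold, 1)
  # keep both annotated genes, half of the rest: fold = (2/6)/(2/10)
  pred <- c("g1", "g2", "g3", "g4", "g5", "g6")
  expect_equal(og_ts_fold_enrichment(pred, ann, genes)$fold,
               (2 / 6) / (2 / 10))
  expect_true(is.na(og_ts_fold_enrichment(character(0), ann, genes)$fold))
  expect_error(og_ts_fold_enrichment(genes, "zz", genes), "no annotated")
})

test_that("Jaccard index and resolution power behave on hand cases", {
  expect_equal(jaccard(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard("a", "b"), 0)
  expect_equal(jaccard(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_warning(expect_equal(jaccard(character(0), character(0)), 1))
  sets <- list(s1 = c("a", "b"), s2 = c("a", "b"), s3 = c("x", "y"),
               s4 = c("x", "z"))
  rp <- resolution_power(sets, c("t1", "t1", "t2", "t2"))
  expect_equal(rp$within, mean(c(1, jaccard(c("x", "y"), c("x", "z")))))
  expect_equal(rp$between, 0)
  expect_equal(rp$score, rp$within)
})

test_that("cross-validation produces exactly k x repeats models", {
  m <- random_fixture(51, n_pathways = 2)
  set.seed(51)
  expr <- stats::setNames(stats::runif(length(m$gene_ids), 5, 50),
                          m$gene_ids)
  keep_all <- method_plugin("parent", function(model, expr, medium, phen)
    list(model = model, growth = fba(model)$objective_value))
  core <- setdiff(m$reaction_ids, m$exchange_ids)
  cv <- cross_validate(keep_all, m, expr, core = core, k = 5, repeats = 15,
                       seed = 3)
  expect_identical(cv$n_models, 75L)
  expect_identical(nrow(cv$folds), 75L)
  expect_identical(formals(cross_validate)$removal_fraction, 0.2)
  # the identity plugin recovers every removed reaction
  expect_true(all(cv$folds$n_recovered == cv$folds$n_removed))
  # a parent-returning plugin draws from a universe it fully covers
  expect_equal(cv$pooled_recovery_p, 1)
  # expression mode reports growth variation instead
  cv2 <- cross_validate(keep_all, m, expr, k = 2, repeats = 2,
                        mode = "expression", seed = 3)
  expect_identical(cv2$n_models, 4L)
  expect_false(is.na(cv2$growth_cv))
})

test_that("noise series are spaced permutations spanning [0, 1]", {
  m <- random_fixture(52, n_pathways = 3, pathway_length = 7,
                      frac_gene_associated = 1)
  set.seed(52)
  expr <- stats::setNames(stats::runif(length(m$gene_ids), 5, 50),
                          m$gene_ids)
  nz <- noise_series(expr, n_sets = 20, seed = 7)
  expect_length(nz$profiles, 20)
  # every profile is an exact permutation of the original values
  for (p in nz$profiles)
    expect_equal(sort(unname(p)), sort(unname(expr)))
  expect_equal(nz$achieved_r[20], 1)
  expect_lt(nz$achieved_r[1], 0.1)
  expect_false(is.unsorted(nz$achieved_r))
  # approximately even spacing
  expect_lt(max(diff(nz$achieved_r)), 0.2)
})

test_that("BH adjustment matches the step-up definition exhaustively", {
  set.seed(53)
  for (n in c(1, 2, 5, 10, 20)) {
    p <- runif(n)
    expect_equal(stats::p.adjust(p, "BH"), bh_stepup(p),
                 info = paste("n", n))
  }
})

test_that("method scoring is direction-aware and order-invariant", {
  raw <- rbind(m1 = c(0.1, 5, 3), m2 = c(0.9, 2, NA))
  rep <- score_methods(raw, direction = c(-1, 1, 1))
  expect_equal(unname(rep$scores["m1", ]), c(1, 1, 1))
  expect_equal(unname(rep$scores["m2", ]), c(0, 0, 0))
  expect_true(rep$flags["m2", 3])
  # permuting method rows permutes scores identically
  rep2 <- score_methods(raw[2:1, ], direction = c(-1, 1, 1))
  expect_equal(rep2$scores["m1", ], rep$scores["m1", ])
  # linkage merge order follows hand-computed Euclidean distances
  raw3 <- rbind(a = c(1, 1, 1), b = c(1, 1, 0.9), c = c(0, 0, 0))
  rep3 <- score_methods(raw3)
  expect_s3_class(rep3$tree, "hclust")
  first_pair <- rownames(raw3)[-rep3$tree$merge[1, ]]
  expect_setequal(first_pair, c("a", "b"))
})
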