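test_that("FASTCC classifies the chain and planted dead ends", {
  m <- example_chain_model()
  rep <- fastcc(m)
  expect_length(rep$blocked, 0)
  expect_setequal(rep$consistent, m$reaction_ids)
  # witness attains epsilon for every consistent reaction
  hit <- apply(abs(rep$witness) >= 0.99 * rep$epsilon, 1, any)
  expect_true(all(hit[rep$consistent]))
  mb <- random_fixture(12, n_blocked = 3)
  expect_setequal(fastcc(mb)$blocked, attr(mb, "blocked_truth"))
})

test_that("FASTCC matches the per-reaction FVA oracle on random fixtures", {
  for (seed in 1:12) {
    m <- random_fixture(seed, n_pathways = 1 + seed %% 3,
                        pathway_length = 2 + seed %% 3,
                        n_blocked = seed %% 4)
    expect_setequal(fastcc(m)$blocked, blocked_brute(m))
  }
})

test_that("removing reactions never unblocks the rest", {
  m <- random_fixture(13, n_pathways = 3, n_blocked = 2)
  parent_blocked <- fastcc(m)$blocked
  keep <- setdiff(m$reaction_ids, sample(setdiff(m$reaction_ids,
                                                 m$objective_id), 2))
  sm <- submodel(m, keep)
  sub_blocked <- fastcc(sm)$blocked
  expect_true(all(intersect(parent_blocked, keep) %in% sub_blocked))
})

test_that("the blocked set is stable across the epsilon range", {
  m <- random_fixture(14, n_blocked = 2)
  base <- fastcc(m, 1e-4)$blocked
  for (eps in c(1e-6, 1e-5, 1e-3))
    expect_setequal(fastcc(m, eps)$blocked, base)
})

test_that("blocked_fraction covers constrained and unconstrained states", {
  m <- example_chain_model()
  expect_equal(blocked_fraction(m), 0)
  # closing the only carbon source blocks the biomass path
  expect_gt(blocked_fraction(m, medium_spec(c(EX_a = 0))), 0)
  # invariant under reaction reordering
  mb <- random_fixture(15, n_blocked = 2)
  perm <- sample(length(mb$reaction_ids))
  mp <- metabolic_model(mb$S[, perm], mb$lb[perm], mb$ub[perm],
                        gpr = mb$gpr[perm], objective_id = mb$objective_id)
  expect_equal(blocked_fraction(mp), blocked_fraction(mb))
})

test_that("consistency reports serialize as TSV", {
  m <- random_fixture(16, n_blocked = 1)
  rep <- fastcc(m)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_consistency_tsv(rep, p)
  df <- read.delim(p)
  expect_setequal(df$reaction_id[df$status == "blocked"], rep$blocked)
  expect_true(all(abs(df$witness_flux[df$status == "consistent"]) >=
                    0.99 * rep$epsilon))
})
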