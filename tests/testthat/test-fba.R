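test_that("bounds follow the genotype, reversibility and environment", {
  u <- chain_universe(3)
  g <- full_genotype(u)
  pb <- build_problem(u, g, chain_env())
  expect_s3_class(pb, "flux_problem")
  # exchange: uptake open for the importable nutrient
  expect_equal(pb$lb[1], -1000)
  expect_equal(pb$ub[1], 1000)
  # irreversible interior reactions
  expect_equal(pb$lb[2:4], rep(0, 3))

  # absent reactions pinned to zero
  g0 <- genotype(u, character(0))
  pb0 <- build_problem(u, g0, chain_env())
  sw <- u$swappable
  expect_equal(pb0$lb[sw], rep(0, sum(sw)))
  expect_equal(pb0$ub[sw], rep(0, sum(sw)))

  # non-importable nutrient: uptake closed
  pb_closed <- build_problem(u, g, growth_environment("none", character(0)))
  expect_equal(pb_closed$lb[1], 0)
})

test_that("biomass optimum equals the stoichiometrically forced yield", {
  u <- chain_universe(3)
  sol <- max_biomass(u, full_genotype(u), chain_env())
  expect_equal(sol$status, "optimal")
  expect_equal(sol$Z, 1000)            # 1:1 yield, limited by uptake bound
  expect_true(max(abs(as.matrix(u$S) %*% sol$v)) < 1e-7)

  # removing one interior step breaks the pathway
  g <- genotype(u, c("R1", "R3"))
  expect_equal(max_biomass(u, g, chain_env())$Z, 0)
})

test_that("optimal Z agrees with the vertex-enumeration oracle on random toys", {
  for (seed in 1:15) {
    u <- random_fba_universe(seed)
    g <- full_genotype(u)
    env <- random_fba_env(u)
    z <- max_biomass(u, g, env)$Z
    expect_equal(z, fba_oracle_Z(u, g, env), tolerance = 1e-8,
                 info = paste("seed", seed))
  }
})

test_that("Z is monotone under genotype supersets", {
  for (seed in 1:20) {
    u <- random_fba_universe(seed, n_rxn = 7)
    env <- random_fba_env(u)
    sw <- which(u$swappable)
    set.seed(seed + 1000)
    small <- sample(sw, 4)
    big <- union(small, sample(sw, 2))
    g_small <- genotype(u, u$rxn_ids[small])
    g_big <- genotype(u, u$rxn_ids[big])
    z1 <- max_biomass(u, g_small, env)$Z
    z2 <- max_biomass(u, g_big, env)$Z
    expect_gte(z2, z1 - 1e-7)
  }
})

test_that("viability is the conjunction over environments", {
  sy <- synth_universe(synth_config(n_nutrients = 2, pathway_length = 2,
                                    n_redundant_routes = 1, core_length = 2,
                                    n_distractors = 0, cofactors = 0))
  u <- sy$universe
  full <- full_genotype(u)
  envs <- sy$environments
  expect_true(is_viable(u, full, envs))

  # genotype that can only use nutrient 1
  only1 <- genotype(u, setdiff(present_reactions(u, full, "metabolic"),
                               c("CAT2_1", "CAT2_2")))
  expect_true(is_viable(u, only1, envs[1]))
  expect_false(is_viable(u, only1, envs[2]))
  expect_false(is_viable(u, only1, envs))
  expect_equal(is_viable(u, only1, envs),
               is_viable(u, only1, envs[1]) && is_viable(u, only1, envs[2]))

  # missing any producer of a biomass precursor
  nocore <- genotype(u, setdiff(present_reactions(u, full, "metabolic"),
                                sy$ground_truth$core[1]))
  expect_false(is_viable(u, nocore, envs[1]))

  expect_error(is_viable(u, full, list()), class = "fm_parse_error")
})

test_that("flux variability brackets zero and flags dead ends", {
  u <- chain_universe(2)
  fv <- flux_variability(u, full_genotype(u), open_exchanges = TRUE,
                         decouple_biomass = TRUE)
  rownames(fv) <- fv$reaction_id
  # interior chain reactions run from 0 up to the uptake bound
  expect_equal(fv[c("R1", "R2"), "min"], c(0, 0))
  expect_equal(fv[c("R1", "R2"), "max"], c(1000, 1000))
  # the exchange imports (negative flux) and cannot secrete
  expect_equal(fv["EX_A0", "min"], -1000)
  expect_equal(fv["EX_A0", "max"], 0)
  # every interval brackets zero
  expect_true(all(fv$min <= 1e-9 & fv$max >= -1e-9))

  # dead-end producer: no consumer for C
  mets <- data.frame(id = c("A_ext", "B", "C"),
                     external = c(TRUE, FALSE, FALSE))
  rxns <- data.frame(id = c("EX_A", "R1", "RDEAD", "BM"),
                     equation = c("A_ext =>", "A_ext => B", "A_ext => C",
                                  "B =>"),
                     role = c("exchange", "metabolic", "metabolic", "biomass"),
                     swappable = c(FALSE, TRUE, TRUE, FALSE))
  u2 <- reaction_universe(mets, rxns)
  fv2 <- flux_variability(u2, full_genotype(u2), reactions = "RDEAD")
  expect_equal(c(fv2$min, fv2$max), c(0, 0))
})

test_that("blocked detection matches construction and reachability", {
  sy <- synth_universe(synth_config(n_nutrients = 2, pathway_length = 2,
                                    n_redundant_routes = 1, core_length = 2,
                                    n_distractors = 3, cofactors = 0))
  expect_equal(sort(blocked_reactions(sy$universe)),
               sy$ground_truth$blocked)
  expect_length(blocked_reactions(chain_universe(4)), 0)
})
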