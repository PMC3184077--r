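test_that("mass balance fixes the ratio along a linear chain", {
  u <- chain_universe(4)
  g <- full_genotype(u)
  cb <- coupling_bounds(u, g, "R1", "R2")
  expect_true(cb$feasible)
  expect_equal(cb$Rmin, 1, tolerance = 1e-9)
  expect_equal(cb$Rmax, 1, tolerance = 1e-9)
  expect_true(fully_coupled(cb))
  # symmetric in the pair order
  expect_true(fully_coupled(coupling_bounds(u, g, "R2", "R1")))
})

test_that("non-unit stoichiometry forces the corresponding ratio", {
  # A -> 2B then B -> C: upstream/downstream ratio is 1/2
  mets <- data.frame(id = c("A_ext", "B", "C"),
                     external = c(TRUE, FALSE, FALSE))
  rxns <- data.frame(id = c("EX_A", "R1", "R2", "BM"),
                     equation = c("A_ext =>", "A_ext => 2 B", "B => C",
                                  "C =>"),
                     role = c("exchange", "metabolic", "metabolic", "biomass"),
                     swappable = c(FALSE, TRUE, TRUE, FALSE))
  u <- reaction_universe(mets, rxns)
  cb <- coupling_bounds(u, full_genotype(u), "R1", "R2")
  expect_equal(cb$Rmin, 0.5, tolerance = 1e-9)
  expect_equal(cb$Rmax, 0.5, tolerance = 1e-9)
  expect_true(fully_coupled(cb))
})

test_that("a branch point breaks full coupling", {
  # one producer, two consumers of B
  mets <- data.frame(id = c("A_ext", "B", "C", "D_ext"),
                     external = c(TRUE, FALSE, FALSE, TRUE))
  rxns <- data.frame(id = c("EX_A", "EX_D", "RP", "RB1", "RB2", "BM"),
                     equation = c("A_ext =>", "D_ext =>", "A_ext => B",
                                  "B => C", "B => D_ext", "C =>"),
                     role = c("exchange", "exchange", rep("metabolic", 3),
                              "biomass"),
                     swappable = c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE),
                     stringsAsFactors = FALSE)
  u <- reaction_universe(mets, rxns)
  cb <- coupling_bounds(u, full_genotype(u), "RP", "RB1")
  expect_true(cb$feasible)
  expect_lt(cb$Rmin, cb$Rmax)
  expect_false(fully_coupled(cb))
  p <- fcs_partition(u, full_genotype(u))
  expect_equal(p$s, 0)
})

test_that("the coupling decision applies the documented tolerance rules", {
  mk <- function(lo, hi) structure(list(Rmin = lo, Rmax = hi,
                                        feasible = TRUE),
                                   class = "coupling_bounds")
  expect_true(fully_coupled(mk(1, 1)))
  expect_false(fully_coupled(mk(0, 0)))        # zero ratio is not coupling
  expect_true(fully_coupled(mk(0.5, 0.5 + 1e-12)))
  expect_false(fully_coupled(mk(0.5, 0.6)))
  expect_false(fully_coupled(structure(list(Rmin = NA, Rmax = NA,
                                            feasible = FALSE),
                                       class = "coupling_bounds")))
})

test_that("chains and unions of chains give the designed partitions", {
  for (k in c(3, 5)) {
    p <- fcs_partition(chain_universe(k), full_genotype(chain_universe(k)))
    expect_equal(p$s, 1)
    expect_equal(p$M, k)
    expect_setequal(p$sets[[1]], paste0("R", 1:k))
  }
  # two independent chains of sizes 3 and 4 in one universe
  sy <- synth_universe(synth_config(n_nutrients = 2, pathway_length = 3,
                                    n_redundant_routes = 2, core_length = 4,
                                    n_distractors = 0, cofactors = 0))
  p <- fcs_partition(sy$universe, full_genotype(sy$universe))
  expect_equal(lapply(p$sets, sort), sy$ground_truth$expected_fcs)
})

test_that("partition matches null-space and Monte-Carlo oracles on reversible toys", {
  set.seed(2024)
  for (seed in 1:8) {
    u <- random_reversible_universe(seed)
    g <- full_genotype(u)
    p <- fcs_partition(u, g)
    net <- analysis_network(u, g, open_exchanges = TRUE,
                            decouple_biomass = TRUE)
    met_idx <- which(net$kind == "metabolic")
    expect_equal(partition_sets(p),
                 classes_to_sets(net$ids[met_idx],
                                 nullspace_classes(net$S, met_idx)),
                 info = paste("nullspace, seed", seed))
    expect_equal(partition_sets(p),
                 classes_to_sets(net$ids[met_idx],
                                 mc_ratio_classes(net$S, met_idx, 2000)),
                 info = paste("ratio sampling, seed", seed))
  }
})

test_that("partition invariants hold and relabeling only permutes sets", {
  sy <- synth_universe(synth_config(n_nutrients = 3, pathway_length = 2,
                                    n_redundant_routes = 2, core_length = 3,
                                    n_distractors = 2))
  u <- sy$universe
  p <- fcs_partition(u, full_genotype(u))
  expect_false(anyDuplicated(unlist(p$sets)) > 0)
  expect_true(all(lengths(p$sets) >= 2))
  expect_equal(p$M, sum(lengths(p$sets)))
  expect_equal(p$s, length(p$sets))

  # reorder the reaction table: same partition as a set of sets
  ord <- rev(seq_along(u$rxn_ids))
  d <- file.path(tempdir(), "perm")
  write_universe(u, d)   # canonical order differs from construction order
  u2 <- read_universe(d)
  p2 <- fcs_partition(u2, full_genotype(u2))
  expect_equal(p$sets, p2$sets)
})

test_that("exhaustive all-pairs mode reproduces the transitivity shortcut", {
  sy <- synth_universe(synth_config(n_nutrients = 2, pathway_length = 2,
                                    n_redundant_routes = 2, core_length = 3,
                                    n_distractors = 2, cofactors = 0))
  u <- sy$universe
  p1 <- fcs_partition(u, full_genotype(u))
  p2 <- fcs_partition(u, full_genotype(u), exhaustive = TRUE)
  expect_equal(p1$sets, p2$sets)
})

test_that("modularity indices summarize a partition", {
  mk <- function(sets) structure(list(sets = sets,
                                      M = sum(lengths(sets)),
                                      s = length(sets)),
                                 class = "fcs_partition")
  expect_equal(modularity_indices(mk(list())), c(M = 0, s = 0))
  expect_equal(modularity_indices(mk(list(letters[1:5]))), c(M = 5, s = 1))
  expect_equal(modularity_indices(mk(list(letters[1:3], letters[4:7]))),
               c(M = 7, s = 2))
})
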