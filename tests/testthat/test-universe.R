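test_that("equation parsing transcribes coefficients, arrows and defaults", {
  eq <- parse_equation("2 A + B <=> C")
  expect_true(eq$reversible)
  expect_equal(eq$coef[c("A", "B", "C")], c(A = -2, B = -1, C = 1))

  eq2 <- parse_equation("A_ext => B")
  expect_false(eq2$reversible)
  expect_equal(eq2$coef[["A_ext"]], -1)
  expect_equal(eq2$coef[["B"]], 1)

  expect_equal(parse_equation("A_ext =>")$coef, c(A_ext = -1))
  expect_error(parse_equation("A B => C"), class = "fm_parse_error")
  expect_error(parse_equation("A - B"), class = "fm_parse_error")
})

test_that("universe construction validates each documented malformation", {
  mets <- data.frame(id = c("A_ext", "B"), external = c(TRUE, FALSE))
  rxns <- data.frame(id = c("EX_A", "R1", "BM"),
                     equation = c("A_ext =>", "A_ext => B", "B =>"),
                     role = c("exchange", "metabolic", "biomass"),
                     swappable = c(FALSE, TRUE, FALSE))
  u <- reaction_universe(mets, rxns)
  expect_s3_class(u, "reaction_universe")
  expect_equal(dim(u$S), c(2L, 3L))
  expect_equal(u$S["A_ext", "R1"], -1)
  expect_equal(u$S["B", "R1"], 1)
  expect_equal(u$biomass_precursors, c(B = 1))

  expect_error(reaction_universe(rbind(mets, mets[1, ]), rxns),
               class = "fm_duplicate_id")
  expect_error(reaction_universe(mets, rbind(rxns, rxns[2, ])),
               class = "fm_duplicate_id")
  bad <- rxns; bad$equation[2] <- "A_ext => Q"
  expect_error(reaction_universe(mets, bad), class = "fm_unknown_metabolite")
  two_bm <- rbind(rxns, data.frame(id = "BM2", equation = "B =>",
                                   role = "biomass", swappable = FALSE))
  expect_error(reaction_universe(mets, two_bm), class = "fm_no_biomass")
  bad_ex <- rxns; bad_ex$equation[1] <- "B =>"
  expect_error(reaction_universe(mets, bad_ex), class = "fm_bad_exchange")
  bad_sw <- rxns; bad_sw$swappable[1] <- TRUE
  expect_error(reaction_universe(mets, bad_sw), class = "fm_parse_error")
})

test_that("write_universe emits canonical TSV and round-trips losslessly", {
  sy <- synth_universe(synth_config(n_nutrients = 2, pathway_length = 2,
                                    n_redundant_routes = 2, core_length = 2,
                                    n_distractors = 2))
  d1 <- file.path(tempdir(), "u1"); d2 <- file.path(tempdir(), "u2")
  write_universe(sy$universe, d1)
  u2 <- read_universe(d1)
  write_universe(u2, d2)
  for (f in c("reactions.tsv", "metabolites.tsv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  # structural equality after the round trip
  expect_setequal(u2$rxn_ids, sy$universe$rxn_ids)
  o <- match(sy$universe$rxn_ids, u2$rxn_ids)
  expect_equal(u2$reversible[o], sy$universe$reversible)
  expect_equal(u2$role[o], sy$universe$role)
  expect_equal(as.matrix(u2$S)[sy$universe$met_ids, sy$universe$rxn_ids],
               as.matrix(sy$universe$S))
})

test_that("canonical TSV output is independent of row insertion order", {
  mets <- data.frame(id = c("A_ext", "B", "C"),
                     external = c(TRUE, FALSE, FALSE))
  rxns <- data.frame(id = c("EX_A", "R2", "R1", "BM"),
                     equation = c("A_ext =>", "B => C", "A_ext => B", "C =>"),
                     role = c("exchange", "metabolic", "metabolic", "biomass"),
                     swappable = c(FALSE, TRUE, TRUE, FALSE))
  d1 <- file.path(tempdir(), "o1"); d2 <- file.path(tempdir(), "o2")
  write_universe(reaction_universe(mets, rxns), d1)
  write_universe(reaction_universe(mets[c(3, 1, 2), ], rxns[c(4, 3, 2, 1), ]), d2)
  for (f in c("reactions.tsv", "metabolites.tsv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("annotation reader accumulates labels and rejects bad input", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("reaction_id\tpathway", "R1\tglycolysis", "R1\tTCA",
               "R2\tTCA"), f)
  ann <- read_annotations(f)
  expect_setequal(ann$R1, c("glycolysis", "TCA"))
  expect_equal(ann$R2, "TCA")

  f_bad <- tempfile(fileext = ".tsv")
  writeLines(c("reaction_id\tpathway", "NOT_A_REACTION\tglycolysis"), f_bad)
  expect_error(read_annotations(f_bad, chain_universe(2)),
               class = "fm_unknown_reaction")
  f2 <- tempfile(fileext = ".tsv")
  writeLines("reaction_id\tpathway", f2)
  expect_error(read_annotations(f2), class = "fm_empty_file")

  f3 <- tempfile(fileext = ".tsv")
  write_annotations(ann, f3)
  back <- read_annotations(f3)
  expect_setequal(names(back), names(ann))
  for (r in names(ann)) expect_setequal(back[[r]], ann[[r]])
})

test_that("environment JSON round-trips and validates importables", {
  envs <- list(growth_environment("glc", c("A0")),
               growth_environment("ac", c("A0")))
  f <- tempfile(fileext = ".json")
  write_environments(envs, f)
  back <- read_environments(f, chain_universe(2))
  expect_equal(length(back), 2L)
  expect_equal(back[[1]]$label, "glc")
  expect_equal(back[[1]]$importable, "A0")

  bad <- list(growth_environment("x", "nope"))
  fb <- tempfile(fileext = ".json")
  write_environments(bad, fb)
  expect_error(read_environments(fb, chain_universe(2)),
               class = "fm_unknown_metabolite")
  fe <- tempfile(fileext = ".json")
  writeLines("[]", fe)
  expect_error(read_environments(fe), class = "fm_empty_file")
})

test_that("minimal SBML import maps species and stoichiometry", {
  skip_if_not_installed("xml2")
  sbml <- '<?xml version="1.0"?>
<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="4">
 <model id="toy">
  <listOfSpecies>
   <species id="A" boundaryCondition="true"/>
   <species id="B" boundaryCondition="false"/>
   <species id="C"/>
  </listOfSpecies>
  <listOfReactions>
   <reaction id="R1" reversible="false">
    <listOfReactants><speciesReference species="A" stoichiometry="2"/></listOfReactants>
    <listOfProducts><speciesReference species="B"/></listOfProducts>
   </reaction>
   <reaction id="R2" reversible="true">
    <listOfReactants><speciesReference species="B"/></listOfReactants>
    <listOfProducts><speciesReference species="C"/></listOfProducts>
   </reaction>
  </listOfReactions>
 </model>
</sbml>'
  f <- tempfile(fileext = ".xml")
  writeLines(sbml, f)
  u <- read_universe(f, dialect = "sbml")
  expect_equal(u$external, c(TRUE, FALSE, FALSE))
  expect_equal(u$S["A", "R1"], -2)
  expect_equal(u$S["B", "R1"], 1)
  expect_false(u$reversible[1])
  expect_true(u$reversible[2])
})
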