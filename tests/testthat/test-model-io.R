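# Reaction-string parsing, TSV and SBML round trips, media files.

test_that("reaction strings parse with printed spacing variants and coefficients", {
  p <- parseReactionString("L_ASP[c] + AKG[c] < = > L_GLU[c] + OAC[c]")
  expect_true(p$reversible)
  expect_equal(p$stoichiometry[c("L_ASP[c]", "AKG[c]", "L_GLU[c]", "OAC[c]")],
               c(-1, -1, 1, 1), ignore_attr = TRUE)

  q <- parseReactionString(
    "2 NAD[c] + H2O[c] + L_HISN[c] - > L_HIS[c] + 3 H[c] + 2 NADH[c]")
  expect_false(q$reversible)
  expect_equal(unname(q$stoichiometry["NAD[c]"]), -2)
  expect_equal(unname(q$stoichiometry["H[c]"]), 3)

  # one-sided (exchange) strings are legal on either side
  expect_length(parseReactionString("GLC[e] <=>")$stoichiometry, 1)
  expect_equal(unname(parseReactionString("-> X[c]")$stoichiometry), 1)

  expect_error(parseReactionString("A[c] -> A[c]"), "both sides")
  expect_error(parseReactionString("A[c] + A[c] -> B[c]"), "duplicated")
  expect_error(parseReactionString("A[c] B[c]"), "arrow")
  expect_error(parseReactionString("A[c] -> B[c] -> C[c]"), "exactly one")
})

test_that("TSV round trip preserves S, bounds, GPRs and objective", {
  fx <- fixtureOnce()
  path <- withr::local_tempfile(fileext = ".tsv")
  writeReactionTable(fx$model, path)
  back <- readReactionTable(path)
  expect_equal(as.matrix(stoichiometricMatrix(back)),
               as.matrix(stoichiometricMatrix(fx$model)))
  expect_equal(reactions(back)$lower, reactions(fx$model)$lower)
  expect_equal(reactions(back)$upper, reactions(fx$model)$upper)
  expect_equal(reactions(back)$reversible, reactions(fx$model)$reversible)
  expect_equal(reactions(back)$gpr, reactions(fx$model)$gpr)
  expect_equal(reactions(back)$objective, reactions(fx$model)$objective)
  expect_identical(genes(back), genes(fx$model))
})

test_that("reaction-table reader reports the offending row and parses GPRs", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(c("id\tname\tequation\tgpr\tsubsystem\tlower\tupper",
                     "R1\tt\tA[e] -> A[c]\tg1\ttransport\t\t",
                     "R2\tx\tB[c] + -> C[c]\t\t\t\t"), collapse = "\n"), path)
  expect_error(readReactionTable(path), "row 2")

  writeLines(paste(c("id\tname\tequation\tgpr\tsubsystem\tlower\tupper",
                     "R1\tilvE\tL_VAL[c] + AKG[c] <=> L_GLU[c] + KIV[c]\t(TTC1870)\tamino acid\t\t"),
                   collapse = "\n"), path)
  m <- readReactionTable(path)
  expect_identical(genes(m), "TTC1870")
  expect_true(reactions(m)$reversible[1])
  expect_equal(reactions(m)$lower[1], -1000)
})

test_that("SBML level 2 version 1 round trip is a fixed point", {
  fx <- fixtureOnce()
  p1 <- withr::local_tempfile(fileext = ".xml")
  p2 <- withr::local_tempfile(fileext = ".xml")
  writeSBML(fx$model, p1)
  back <- readSBML(p1)
  expect_equal(as.matrix(stoichiometricMatrix(back)),
               as.matrix(stoichiometricMatrix(fx$model)))
  expect_equal(reactions(back)$lower, reactions(fx$model)$lower)
  expect_equal(reactions(back)$gpr, reactions(fx$model)$gpr)
  expect_equal(reactions(back)$objective, reactions(fx$model)$objective)
  expect_identical(genes(back), genes(fx$model))
  met <- metabolites(back)
  expect_equal(met$formula[met$id == "GLC[c]"], "C6H12O6")
  # writing the re-read model reproduces the file byte for byte
  writeSBML(back, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("SBML reader rejects other dialects and tolerates missing GPR notes", {
  p <- withr::local_tempfile(fileext = ".xml")
  writeLines(c('<?xml version="1.0"?>',
               '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
               '</sbml>'), p)
  expect_error(readSBML(p), "dialect")

  writeLines(c('<?xml version="1.0"?>',
               '<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="1">',
               '<model id="m"><listOfSpecies>',
               '<species id="M_A_c" compartment="c"/>',
               '</listOfSpecies><listOfReactions>',
               '<reaction id="SINK_A" reversible="false">',
               '<listOfReactants><speciesReference species="M_A_c"/></listOfReactants>',
               '</reaction></listOfReactions></model></sbml>'), p)
  expect_warning(m <- readSBML(p), "GENE_ASSOCIATION")
  expect_equal(nrow(reactions(m)), 1)
  expect_identical(reactions(m)$gpr, "")
  expect_equal(reactions(m)$lower[1], 0)   # irreversible default bounds
})

test_that("media files round trip in JSON and YAML; empty file closes the medium", {
  fx <- fixtureOnce()
  for (ext in c(".json", ".yml")) {
    path <- withr::local_tempfile(fileext = ext)
    writeMedium(fx$tm, path)
    back <- readMedium(path, model = fx$model)
    expect_identical(back@name, fx$tm@name)
    expect_equal(back@bounds, fx$tm@bounds)
    expect_identical(back@unconstrained, fx$tm@unconstrained)
  }
  empty <- withr::local_tempfile(fileext = ".json")
  writeLines("", empty)
  med <- readMedium(empty)
  expect_equal(nrow(med@bounds), 0)
  closed <- applyMedium(chainModel(), med)
  expect_gte(reactions(closed)$lower[1], 0)     # all exchanges shut to uptake
  sol <- solveFBA(closed)
  expect_equal(objectiveValue(sol), 0, tolerance = 1e-9)

  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"name":"x","bounds":{"EX_NOPE":[-5,0]}}', bad)
  expect_error(readMedium(bad, model = fx$model), "EX_NOPE")
})
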