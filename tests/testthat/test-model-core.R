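# Model container, stoichiometric matrix, GPR logic, mass balance, units.

test_that("stoichiometric matrix columns follow the reaction definitions", {
  m <- metabolicModel(data.frame(id = "R1", equation = "A[c] -> B[c]"))
  S <- as.matrix(stoichiometricMatrix(m))
  expect_equal(S["A[c]", "R1"], -1)
  expect_equal(S["B[c]", "R1"], 1)

  # glutamine synthetase: every substrate -1, every product +1
  m2 <- metabolicModel(data.frame(
    id = "R205",
    equation = "L_GLU[c] + ATP[c] + NH4[c] -> L_GLN[c] + ADP[c] + Pi[c] + H[c]"))
  S2 <- as.matrix(stoichiometricMatrix(m2))[, 1]
  expect_equal(S2[c("L_GLU[c]", "ATP[c]", "NH4[c]")], c(-1, -1, -1),
               ignore_attr = TRUE)
  expect_equal(S2[c("L_GLN[c]", "ADP[c]", "Pi[c]", "H[c]")], c(1, 1, 1, 1),
               ignore_attr = TRUE)
})

test_that("S equals an independent row-wise per-metabolite reconstruction", {
  set.seed(42)
  for (rep in 1:3) {
    # random 10-metabolite x 12-reaction table built directly in the test
    mets <- sprintf("M%d[c]", 1:10)
    eqs <- vapply(1:12, function(j) {
      pair <- sample(mets, 2)
      cf <- sample(1:3, 2, replace = TRUE)
      sprintf("%d %s %s %d %s", cf[1], pair[1],
              sample(c("->", "<=>"), 1), cf[2], pair[2])
    }, character(1))
    tab <- data.frame(id = sprintf("R%02d", 1:12), equation = eqs,
                      stringsAsFactors = FALSE)
    m <- metabolicModel(tab)
    S <- as.matrix(stoichiometricMatrix(m))
    # row-wise scan: for each metabolite, find its coefficient in each
    # reaction string independently of the matrix builder
    for (met in metabolites(m)$id) {
      row <- vapply(seq_len(nrow(tab)), function(j) {
        p <- parseReactionString(tab$equation[j])$stoichiometry
        if (met %in% names(p)) unname(p[met]) else 0
      }, numeric(1))
      expect_equal(unname(S[met, ]), row)
    }
  }
})

test_that("GPR evaluation handles isozymes, complexes and empty rules", {
  isozyme <- parseGpr("(TTC0049 or TTC0045)")
  expect_true(evaluateGpr(isozyme, deleted = "TTC0049"))
  expect_false(evaluateGpr(isozyme, deleted = c("TTC0049", "TTC0045")))
  complexg <- parseGpr("(A and B)")
  expect_false(evaluateGpr(complexg, deleted = "B"))
  expect_true(evaluateGpr(NULL, deleted = c("anything")))
  nested <- parseGpr("(A and (B or C)) or D")
  expect_true(evaluateGpr(nested, deleted = c("B")))
  expect_false(evaluateGpr(nested, deleted = c("B", "C", "D")))
  expect_setequal(gprLeaves(nested), c("A", "B", "C", "D"))
  # canonical string form re-parses to the same truth table
  rt <- parseGpr(gprToString(nested))
  for (del in list(character(0), "A", "D", c("A", "D"), c("B", "C")))
    expect_identical(evaluateGpr(rt, del), evaluateGpr(nested, del))
})

test_that("GPR evaluation is monotone in the deleted set", {
  set.seed(7)
  gs <- paste0("g", 1:6)
  rules <- c("g1", "(g1 or g2)", "(g1 and g2)",
             "((g1 and g2) or (g3 and g4))",
             "(g1 or (g2 and (g3 or g4)) or g5)")
  for (rule in rules) {
    tree <- parseGpr(rule)
    for (it in 1:20) {
      small <- sample(gs, sample(0:4, 1))
      big <- union(small, sample(gs, sample(0:4, 1)))
      if (!evaluateGpr(tree, small)) expect_false(evaluateGpr(tree, big))
    }
  }
})

test_that("mass-balance checking flags exactly the planted imbalance", {
  tab <- data.frame(
    id = c("R_OK", "R_BAD", "R_UNK", "EX_A"),
    equation = c("A[c] -> 2 B[c]",       # C6H12O6 -> 2 C3H6O3: balanced
                 "A[c] -> B[c]",         # carbon deficit 3
                 "A[c] -> X[c]",         # X has no formula
                 "A[e] <=>"),
    stringsAsFactors = FALSE)
  m <- metabolicModel(tab, formulas = c("A[c]" = "C6H12O6", "B[c]" = "C3H6O3",
                                        "A[e]" = "C6H12O6"))
  rep <- checkMassBalance(m)
  expect_equal(rep$status[rep$id == "R_OK"], "balanced")
  expect_equal(rep$status[rep$id == "R_BAD"], "imbalanced")
  expect_match(rep$imbalance[rep$id == "R_BAD"], "C:-3")
  expect_equal(rep$status[rep$id == "R_UNK"], "unchecked")
  expect_equal(rep$status[rep$id == "EX_A"], "exempt")

  # a 20-reaction synthetic model with one planted defect
  n <- 20
  eqs <- c(sprintf("M%d[c] -> M%d[c]", 1:(n - 1), 2:n), "M1[c] -> 2 M2[c]")
  big <- metabolicModel(
    data.frame(id = sprintf("R%02d", 1:n), equation = eqs),
    formulas = stats::setNames(rep("C2H4O2", n), sprintf("M%d[c]", 1:n)))
  repb <- checkMassBalance(big)
  expect_identical(repb$id[repb$status == "imbalanced"], "R20")
})

test_that("OD to DCW conversion is the fixed linear factor", {
  expect_equal(odToDcw(1.0), 0.34)
  expect_equal(odToDcw(0), 0)
  expect_equal(odToDcw(2.0), 0.68)
  expect_error(odToDcw(-0.1), "non-negative")
})

test_that("model validity rejects inconsistent objects", {
  m <- chainModel()
  bad <- m
  bad@rxns$lower[1] <- 5; bad@rxns$upper[1] <- -5
  expect_error(methods::validObject(bad), "lower bound")
  expect_error(metabolicModel(data.frame(id = c("R1", "R1"),
                                         equation = c("A[c] ->", "B[c] ->"))),
               "duplicated reaction id")
  expect_error(metabolicModel(data.frame(id = "R1", equation = "A -> B")),
               "compartment suffix")
})
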