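# FBA / FVA engines against analytic and enumeration oracles.

test_that("single-path yield: Z equals the uptake bound", {
  sol <- solveFBA(chainModel(uptake = 10))
  expect_equal(objectiveValue(sol), 10, tolerance = 1e-9)
  expect_identical(solutionStatus(sol), "optimal")
})

test_that("planted two-chain optimum follows the min-ratio formula", {
  pn <- generatePlantedNetwork(nChains = 2, uptake = c(10, 6),
                               yield = c(0.5, 1), biomassCoef = c(1, 2),
                               chainLengths = c(1, 1),
                               orParalog = c(FALSE, FALSE),
                               andComplex = c(FALSE, FALSE))
  expect_equal(pn$mu, 3)                         # min(10*0.5/1, 6*1/2)
  sol <- solveFBA(pn$model)
  expect_equal(objectiveValue(sol), 3, tolerance = 1e-8)
})

test_that("optimal solutions satisfy steady state and all bounds", {
  fx <- fixtureOnce()
  for (med in list(fx$dmm, fx$tm)) {
    m <- applyMedium(fx$model, med, ngam = 14)
    sol <- solveFBA(m)
    v <- fluxes(sol)[reactions(m)$id]
    expect_lt(max(abs(as.matrix(stoichiometricMatrix(m)) %*% v)), 1e-6)
    expect_true(all(v >= reactions(m)$lower - 1e-6))
    expect_true(all(v <= reactions(m)$upper + 1e-6))
  }
})

test_that("FBA matches exhaustive vertex enumeration on small random LPs", {
  for (seed in 1:12) {
    lp <- randomBoundedFbaLike(seed)
    got <- thermoflux:::simplexLP(lp$obj, lp$A, rep(0, nrow(lp$A)),
                                  lp$lb, lp$ub, maximize = TRUE)
    expect_identical(got$status, "optimal")
    want <- vertexEnumOptimum(lp$obj, lp$A, lp$lb, lp$ub)
    expect_equal(got$objective, want, tolerance = 1e-8)
  }
})

test_that("closed medium gives zero growth; NGAM floor makes it infeasible", {
  fx <- fixtureOnce()
  closed <- mediumSpec("closed")
  sol0 <- solveFBA(applyMedium(fx$model, closed, ngam = 0))
  expect_equal(objectiveValue(sol0), 0, tolerance = 1e-9)
  solN <- solveFBA(applyMedium(fx$model, closed, ngam = 14))
  expect_identical(solutionStatus(solN), "infeasible")
  expect_equal(objectiveValue(solN), 0)          # reported as growth 0
})

test_that("applyMedium caps oxygen uptake and rejects non-exchange ids", {
  fx <- fixtureOnce()
  m <- applyMedium(fx$model, fx$dmm, ngam = 14)
  r <- reactions(m)
  expect_equal(r$lower[r$id == "EX_O2"], -10)
  expect_equal(r$lower[r$id == "NGAM"], 14)
  expect_equal(r$lower[r$id == "EX_LEU"], 0)     # unlisted exchange closed
  sol <- solveFBA(m)
  expect_gte(-fluxes(sol)["EX_O2"], 0)
  expect_lte(-fluxes(sol)["EX_O2"], 10 + 1e-9)
  expect_error(applyMedium(fx$model, mediumSpec("bad", list(GLYC = c(-1, 1)))),
               "non-exchange")
})

test_that("FVA collapses to the FBA flux at a unique optimum", {
  m <- chainModel(uptake = 10)
  sol <- solveFBA(m)
  fva <- runFVA(m, zObj = objectiveValue(sol))
  for (k in seq_len(nrow(fva@ranges))) {
    expect_equal(fva@ranges$min[k], unname(fluxes(sol)[fva@ranges$id[k]]),
                 tolerance = 1e-6)
    expect_equal(fva@ranges$max[k], fva@ranges$min[k], tolerance = 1e-6)
  }
})

test_that("two identical parallel paths each range over [0, total]", {
  m <- parallelPathsModel(uptake = 6)
  sol <- solveFBA(m)
  expect_equal(objectiveValue(sol), 6, tolerance = 1e-9)
  fva <- runFVA(m, zObj = 6)
  for (id in c("P1", "P2")) {
    k <- which(fva@ranges$id == id)
    expect_equal(fva@ranges$min[k], 0, tolerance = 1e-6)
    expect_equal(fva@ranges$max[k], 6, tolerance = 1e-6)
  }
})

test_that("FVA sandwich: every FBA flux lies inside its FVA range", {
  fx <- fixtureOnce()
  for (med in list(fx$dmm, fx$tm)) {
    m <- applyMedium(fx$model, med, ngam = 14)
    sol <- solveFBA(m)
    fva <- runFVA(m, zObj = objectiveValue(sol))
    v <- fluxes(sol)[fva@ranges$id]
    expect_true(all(fva@ranges$min - 1e-6 <= v))
    expect_true(all(v <= fva@ranges$max + 1e-6))
    expect_true(all(fva@ranges$min <= fva@ranges$max + 1e-9))
    r <- reactions(m)[match(fva@ranges$id, reactions(m)$id), ]
    expect_true(all(fva@ranges$min >= r$lower - 1e-6))
    expect_true(all(fva@ranges$max <= r$upper + 1e-6))
  }
})

test_that("scaling all exchange bounds scales the optimum (LP homogeneity)", {
  fx <- fixtureOnce()
  base <- solveFBA(applyMedium(fx$model, fx$dmm, ngam = 0))
  for (k in c(0.5, 2)) {
    b <- fx$dmm@bounds
    b$lower <- b$lower * k; b$upper <- b$upper * k
    scaled <- mediumSpec("scaled", b, fx$dmm@unconstrained)
    m <- applyMedium(fx$model, scaled, ngam = 0)
    # unconstrained mineral exchanges scale too
    j <- match(fx$dmm@unconstrained, reactions(m)$id)
    m@rxns$lower[j] <- -1000 * k; m@rxns$upper[j] <- 1000 * k
    sol <- solveFBA(m)
    expect_equal(objectiveValue(sol), k * objectiveValue(base),
                 tolerance = 1e-6)
  }
})

test_that("unbounded objectives are reported as such", {
  m <- metabolicModel(data.frame(
    id = c("EX_A", "GROWTH"),
    equation = c("A[e] <=>", "A[e] ->"),
    lower = c(-Inf, 0), upper = c(Inf, Inf)), objective = "GROWTH")
  # truly unbounded uptake through the open exchange
  sol <- solveFBA(m)
  expect_identical(solutionStatus(sol), "unbounded")
})
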