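# Biomass assembly from compositional data.

test_that("single amino acid closed form and linearity hold", {
  # 100 mol% glycine at protein fraction 0.5: 0.5*1000/(75.07-18.02)
  coef <- aminoAcidCoefficients(c(glycine = 100), 0.5)
  expect_equal(unname(coef), 0.5 * 1000 / (75.07 - 18.02), tolerance = 1e-12)
  expect_equal(unname(coef), 8.764, tolerance = 1e-3)
  # doubling the protein fraction doubles every coefficient
  mix <- c(glycine = 40, alanine = 35, leucine = 25)
  expect_equal(aminoAcidCoefficients(mix, 0.8),
               2 * aminoAcidCoefficients(mix, 0.4))
  expect_error(aminoAcidCoefficients(c(unobtainium = 100), 0.5),
               "unknown amino acid")
})

test_that("equal-mix amino-acid coefficients match a hand recomputation", {
  molpct <- stats::setNames(rep(5, 20), names(thermoflux:::AA_MW))
  got <- aminoAcidCoefficients(molpct, 0.55)
  # independent spreadsheet-style recomputation from first principles
  res_mw <- c(89.09, 174.20, 132.12, 133.10, 121.16, 147.13, 146.15, 75.07,
              155.15, 131.17, 131.17, 146.19, 149.21, 165.19, 115.13, 105.09,
              119.12, 204.23, 181.19, 117.15) - 18.02
  mean_res <- mean(res_mw)            # equal mole fractions
  expect_equal(unname(got), rep(0.55 * 1000 * 0.05 / (mean_res), 20),
               tolerance = 1e-12)
  # total protein mass reconstructed from the coefficients
  expect_equal(sum(got * res_mw) / 1000, 0.55, tolerance = 1e-12)
})

test_that("GC content fixes the nucleotide split and mass closes", {
  eq <- nucleotideCoefficients(0.5, 0.03, 0.12)
  frac <- eq$dna / sum(eq$dna)
  expect_equal(unname(frac), rep(0.25, 4), tolerance = 1e-12)

  nt <- nucleotideCoefficients(0.694, 0.031, 0.12)
  dfrac <- nt$dna / sum(nt$dna)
  expect_equal(unname(dfrac["dGMP"]), 0.347, tolerance = 1e-12)
  expect_equal(unname(dfrac["dAMP"]), 0.153, tolerance = 1e-12)
  # DNA mass reconstructed from coefficients equals the input fraction
  mw <- c(dAMP = 313.21, dCMP = 289.18, dGMP = 329.21, dTMP = 304.20)
  expect_equal(sum(nt$dna * mw[names(nt$dna)]) / 1000, 0.031,
               tolerance = 0.001 * 0.031)
  expect_error(nucleotideCoefficients(1.2, 0.03, 0.12), "between 0 and 1")
})

test_that("fatty-acid coefficients follow the residue-weight scheme", {
  one <- fattyAcidCoefficients(c("iso-C15:0" = 100), 0.1)
  expect_equal(unname(one), 0.1 * 1000 / (242.40 - 18.02), tolerance = 1e-12)
  mix <- c("iso-C15:0" = 50, "iso-C17:0" = 50)
  got <- fattyAcidCoefficients(mix, 0.2)
  denom <- 0.5 * (242.40 - 18.02) + 0.5 * (270.45 - 18.02)
  expect_equal(unname(got), rep(0.2 * 1000 * 0.5 / denom, 2), tolerance = 1e-12)
  expect_equal(fattyAcidCoefficients(mix, 0.3), 3 * fattyAcidCoefficients(mix, 0.1))
})

test_that("assembled biomass carries the GAM ATP cost and closes on mass", {
  fx <- fixtureOnce()
  eq <- assembleBiomass(fx$composition)
  expect_s4_class(eq, "BiomassEquation")
  expect_equal(eq@gam, 58.34)
  expect_equal(unname(eq@precursors["ATP[c]"]), 58.34)   # GAM only: RNA drains NMPs
  expect_equal(unname(eq@products["ADP[c]"]), 58.34)
  expect_true(all(eq@precursors > 0))
  # block coefficients land on the right metabolites unchanged
  aa <- aminoAcidCoefficients(fx$composition$amino_acid_molpct, 0.55)
  expect_equal(unname(eq@precursors["L_LEU[c]"]), unname(aa["leucine"]))
  expect_equal(unname(eq@precursors["L_GLY[c]"]), unname(aa["glycine"]))
  fa <- fattyAcidCoefficients(fx$composition$fatty_acid_molpct, 0.10)
  expect_equal(unname(eq@precursors["FA_ISO_C15_0[c]"]),
               unname(fa["iso-C15:0"]))
  # independent mass closure within 1%: protein + lipid + nucleic acids +
  # lumped wall/pool, each reconstructed from its own block
  nt <- nucleotideCoefficients(0.694, 0.03, 0.12)
  mass <- sum(aa * (thermoflux:::AA_MW[names(aa)] - 18.02)) / 1000 +
    sum(fa * (thermoflux:::FA_MW[names(fa)] - 18.02)) / 1000 +
    sum(nt$dna * thermoflux:::DNMP_RESIDUE_MW[names(nt$dna)]) / 1000 +
    sum(nt$rna * thermoflux:::NMP_RESIDUE_MW[names(nt$rna)]) / 1000 +
    0.15 + 0.05
  expect_equal(mass, 1, tolerance = 0.01)
})

test_that("biomass equation is linear in each mass-fraction block", {
  fx <- fixtureOnce()
  tab <- fx$composition
  a1 <- aminoAcidCoefficients(tab$amino_acid_molpct, 0.5)
  a2 <- aminoAcidCoefficients(tab$amino_acid_molpct, 0.25)
  expect_equal(a1, 2 * a2)
  n1 <- nucleotideCoefficients(tab$gc_content, 0.04, 0.10)
  n2 <- nucleotideCoefficients(tab$gc_content, 0.02, 0.05)
  expect_equal(n1$dna, 2 * n2$dna)
  expect_equal(n1$rna, 2 * n2$rna)
})

test_that("assembled biomass grows on the fixture and each precursor is limiting", {
  # attach the full assembled biomass to a supply skeleton: every precursor
  # importable; growth is finite, and removing any single supply kills it
  fx <- fixtureOnce()
  eq <- assembleBiomass(fx$composition)
  pre <- setdiff(names(eq@precursors), c("ATP[c]", "H2O[c]"))
  rows <- data.frame(id = character(0), equation = character(0),
                     stringsAsFactors = FALSE)
  for (p in pre) {
    base <- sub("\\[c\\]$", "", p)
    rows <- rbind(rows,
                  data.frame(id = paste0("EX_", base),
                             equation = sprintf("%s[e] <=>", base)),
                  data.frame(id = paste0("T_", base),
                             equation = sprintf("%s[e] -> %s", base, p)))
  }
  rows <- rbind(rows,
                data.frame(id = "EX_ATP", equation = "ATP[e] <=>"),
                data.frame(id = "T_ATP", equation = "ATP[e] + H2O[c] -> ATP[c]"),
                data.frame(id = "EX_H2O", equation = "H2O[e] <=>"),
                data.frame(id = "T_H2O", equation = "H2O[e] <=> H2O[c]"),
                data.frame(id = "SINK_ADP", equation = "ADP[c] ->"),
                data.frame(id = "SINK_PI", equation = "Pi[c] ->"),
                data.frame(id = "SINK_H", equation = "H[c] ->"))
  m <- metabolicModel(rows)
  m <- addBiomass(m, eq)
  rich <- richMedium(m)
  mu <- objectiveValue(solveFBA(applyMedium(m, rich)))
  expect_gt(mu, 0)
  for (p in pre[c(1, 8, length(pre))]) {
    base <- sub("\\[c\\]$", "", p)
    cut <- setBounds(m, paste0("EX_", base), lower = 0, upper = 0)
    med <- mediumSpec("cut", unconstrained = setdiff(rich@unconstrained,
                                                     paste0("EX_", base)))
    expect_equal(objectiveValue(solveFBA(applyMedium(cut, med))), 0,
                 tolerance = 1e-8, label = p)
  }
})

test_that("mass-closure violations abort assembly with the gap reported", {
  fx <- fixtureOnce()
  tab <- fx$composition
  # corrupt the cell-wall pseudo-residue path by remapping it onto a real
  # metabolite while keeping fractions: closure must now fail
  bad <- tab
  bad$macromolecule_mass_fractions["protein"] <- 0.10
  bad$macromolecule_mass_fractions["cell_wall"] <- 0.60
  # still sums to 1, but now assembly reconstructs the mass correctly, so
  # closure holds; instead break closure via an inconsistent override table
  expect_silent(assembleBiomass(bad))
  molpct <- tab$amino_acid_molpct
  corrupt <- compositionTable(molpct, tab$fatty_acid_molpct,
                              tab$macromolecule_mass_fractions,
                              tab$gc_content, tab$gam_atp)
  class(corrupt) <- "CompositionTable"
  corrupt$macromolecule_mass_fractions <- tab$macromolecule_mass_fractions
  corrupt$macromolecule_mass_fractions[["other"]] <- -0.2   # inconsistent block
  expect_error(assembleBiomass(corrupt), "closure")
})

test_that("composition comparison reports signed elementwise deltas", {
  fx <- fixtureOnce()
  tab <- fx$composition
  same <- compareCompositions(tab, tab)
  expect_true(all(same$amino_acids$delta == 0))
  expect_true(all(same$summary$total_abs_delta == 0))

  swapped <- tab
  swapped$amino_acid_molpct[c("leucine", "glycine")] <-
    tab$amino_acid_molpct[c("glycine", "leucine")]
  swapped <- compositionTable(swapped$amino_acid_molpct, tab$fatty_acid_molpct,
                              tab$macromolecule_mass_fractions,
                              tab$gc_content, tab$gam_atp)
  cmp <- compareCompositions(tab, swapped)
  nz <- cmp$amino_acids[cmp$amino_acids$delta != 0, ]
  expect_equal(nrow(nz), 2)
  expect_equal(sum(nz$delta), 0)
  expect_equal(abs(nz$delta[1]), abs(nz$delta[2]))
  # deltas are plain subtraction
  expect_equal(cmp$amino_acids$delta,
               unname(swapped$amino_acid_molpct[cmp$amino_acids$component] -
                        tab$amino_acid_molpct[cmp$amino_acids$component]))

  broken <- tab
  names(broken$fatty_acid_molpct)[1] <- "C13:0"
  expect_error(compareCompositions(tab, broken), "key mismatch")
})
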