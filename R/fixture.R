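# A curated ~40-reaction thermophile-like fixture.
#
# Emulates the distinctive metabolic features of Thermus-like thermophiles
# at desk scale: ATP-coupled ABC sugar uptake (no PTS), a lumped
# glycolysis/TCA/oxidative-phosphorylation backbone with an explicit NGAM
# reaction, branched-chain amino-acid (BCAA) uptake and ilvE-style
# transamination feeding branched-chain fatty-acid (BCFA) synthesis, and a
# linear carotenoid chain of single-gene steps ending in a
# thermozeaxanthin-like membrane component that biomass requires. Two media
# are shipped: a glucose minimal (DMM-like) and a complex (TM-like) medium
# supplying trehalose, BCAAs and glutamate.

fixtureReactionTable <- function() {
  r <- function(id, eq, gpr = "", sub = "", name = id, lower = NA, upper = NA, obj = 0)
    data.frame(id = id, name = name, equation = eq, gpr = gpr, subsystem = sub,
               lower = lower, upper = upper, objective = obj,
               stringsAsFactors = FALSE)
  rbind(
    # exchanges (media set the actual bounds)
    r("EX_GLC", "GLC[e] <=>", sub = "exchange", name = "glucose exchange"),
    r("EX_TRE", "TRE[e] <=>", sub = "exchange", name = "trehalose exchange"),
    r("EX_O2",  "O2[e] <=>",  sub = "exchange", name = "oxygen exchange"),
    r("EX_NH4", "NH4[e] <=>", sub = "exchange", name = "ammonium exchange"),
    r("EX_H2O", "H2O[e] <=>", sub = "exchange", name = "water exchange"),
    r("EX_H",   "H[e] <=>",   sub = "exchange", name = "proton exchange"),
    r("EX_CO2", "CO2[e] <=>", sub = "exchange", name = "CO2 exchange"),
    r("EX_LEU", "L_LEU[e] <=>", sub = "exchange", name = "L-leucine exchange"),
    r("EX_VAL", "L_VAL[e] <=>", sub = "exchange", name = "L-valine exchange"),
    r("EX_ILE", "L_ILE[e] <=>", sub = "exchange", name = "L-isoleucine exchange"),
    r("EX_GLU", "L_GLU[e] <=>", sub = "exchange", name = "L-glutamate exchange"),
    # transport: ABC importers hydrolyse ATP (no PTS in Thermus-like cells)
    r("T_GLC", "GLC[e] + ATP[c] + H2O[c] -> GLC[c] + ADP[c] + Pi[c] + H[c]",
      "TTX_GLCA", "transport", "glucose ABC transporter"),
    r("T_TRE", "TRE[e] + ATP[c] + H2O[c] -> TRE[c] + ADP[c] + Pi[c] + H[c]",
      "TTX_TREA", "transport", "trehalose ABC transporter"),
    r("T_LEU", "L_LEU[e] + ATP[c] + H2O[c] -> L_LEU[c] + ADP[c] + Pi[c] + H[c]",
      "TTX_LIVJ", "transport", "leucine ABC transporter"),
    r("T_VAL", "L_VAL[e] + ATP[c] + H2O[c] -> L_VAL[c] + ADP[c] + Pi[c] + H[c]",
      "TTX_LIVK", "transport", "valine ABC transporter"),
    r("T_ILE", "L_ILE[e] + ATP[c] + H2O[c] -> L_ILE[c] + ADP[c] + Pi[c] + H[c]",
      "TTX_LIVM", "transport", "isoleucine ABC transporter"),
    r("T_GLU", "L_GLU[e] + ATP[c] + H2O[c] -> L_GLU[c] + ADP[c] + Pi[c] + H[c]",
      "TTX_GLTT", "transport", "glutamate ABC transporter"),
    r("T_O2",  "O2[e] <=> O2[c]",   sub = "transport", name = "O2 diffusion"),
    r("T_NH4", "NH4[e] <=> NH4[c]", sub = "transport", name = "ammonium transport"),
    r("T_H2O", "H2O[e] <=> H2O[c]", sub = "transport", name = "water diffusion"),
    r("T_H",   "H[c] <=> H[e]",     sub = "transport", name = "proton antiport"),
    r("T_CO2", "CO2[c] <=> CO2[e]", sub = "transport", name = "CO2 diffusion"),
    # central carbon (lumped)
    r("TREH", "TRE[c] + H2O[c] -> 2 GLC[c]", "TTX_AGLA", "carbohydrates",
      "alpha-glucosidase (trehalase)"),
    r("GLYC", "GLC[c] + 2 ADP[c] + 2 Pi[c] + 2 NAD[c] -> 2 PYR[c] + 2 ATP[c] + 2 NADH[c] + 2 H[c] + 2 H2O[c]",
      "TTX_GLK", "carbohydrates", "glycolysis (lumped)"),
    r("PDH", "PYR[c] + NAD[c] -> ACCOA[c] + CO2[c] + NADH[c]",
      "TTX_PDHA", "carbohydrates", "pyruvate dehydrogenase (lumped)"),
    r("TCA", "ACCOA[c] + 3 NAD[c] + ADP[c] + Pi[c] + 2 H2O[c] -> 2 CO2[c] + 3 NADH[c] + ATP[c] + 3 H[c]",
      "TTX_GLTA", "energy and cofactors", "TCA cycle (lumped)"),
    r("AKGS", "PYR[c] + ACCOA[c] + NAD[c] + H2O[c] -> AKG[c] + NADH[c] + H[c]",
      "TTX_ICD", "energy and cofactors", "2-oxoglutarate synthesis (lumped)"),
    r("OXPHOS", "2 NADH[c] + O2[c] + 4 ADP[c] + 4 Pi[c] + 2 H[c] -> 2 NAD[c] + 4 ATP[c] + 6 H2O[c]",
      "(TTX_NUOA and TTX_ATPA)", "energy and cofactors",
      "oxidative phosphorylation (P/O = 2)"),
    r("THD", "NADH[c] + NADP[c] -> NAD[c] + NADPH[c]",
      "TTX_PNTA", "energy and cofactors", "transhydrogenase"),
    r("NGAM", "ATP[c] + H2O[c] -> ADP[c] + Pi[c] + H[c]", "",
      "energy and cofactors", "ATP maintenance (non-growth associated)"),
    # amino acids
    r("GDH", "AKG[c] + NH4[c] + NADPH[c] -> L_GLU[c] + NADP[c] + H2O[c]",
      "TTX_GDHA", "amino acid", "glutamate dehydrogenase"),
    r("VALS", "2 PYR[c] + L_GLU[c] + NADPH[c] -> L_VAL[c] + AKG[c] + NADP[c] + CO2[c] + H2O[c]",
      "TTX_ILVC", "amino acid", "valine biosynthesis (lumped)"),
    r("ILES", "2 PYR[c] + ACCOA[c] + L_GLU[c] + NADPH[c] -> L_ILE[c] + AKG[c] + NADP[c] + 2 CO2[c]",
      "TTX_ILVD", "amino acid", "isoleucine biosynthesis (lumped)"),
    r("LEUS", "2 PYR[c] + ACCOA[c] + L_GLU[c] + NADPH[c] -> L_LEU[c] + AKG[c] + NADP[c] + 2 CO2[c] + H2O[c]",
      "TTX_LEUA", "amino acid", "leucine biosynthesis (lumped)"),
    r("LEU_TA", "L_LEU[c] + AKG[c] <=> KIC[c] + L_GLU[c]",
      "TTX_ILVE", "amino acid", "branched-chain aminotransferase"),
    # lipids: BCFA from the leucine skeleton (vor/fab route)
    r("BCFAS", "KIC[c] + 5 ACCOA[c] + 10 NADPH[c] + 5 ATP[c] + H2O[c] -> BCFA[c] + CO2[c] + 10 NADP[c] + 5 ADP[c] + 5 Pi[c]",
      "(TTX_VORA and (TTX_FABF or TTX_FABF2))", "lipids",
      "branched-chain fatty-acid synthesis (lumped)"),
    # carotenoids: linear single-gene chain to a thermozeaxanthin-like product
    r("IPPS", "PYR[c] + ACCOA[c] + ATP[c] + NADPH[c] -> IPP[c] + ADP[c] + Pi[c] + NADP[c] + CO2[c]",
      "TTX_IDI", "carotenoids", "isopentenyl diphosphate synthesis (lumped)"),
    r("CRT1", "8 IPP[c] + 2 ATP[c] -> PHYT[c] + 2 ADP[c] + 2 Pi[c]",
      "TTX_CRTB", "carotenoids", "phytoene synthase (lumped)"),
    r("CRT2", "PHYT[c] + 4 NAD[c] -> ZEAX[c] + 4 NADH[c] + 4 H[c]",
      "TTX_CRTI", "carotenoids", "desaturation/cyclation to zeaxanthin (lumped)"),
    r("CRT3", "ZEAX[c] + GLC[c] + ATP[c] -> ZGLC[c] + ADP[c] + Pi[c]",
      "TTX_CRUC", "carotenoids", "zeaxanthin glycosyltransferase"),
    r("CRT4", "ZGLC[c] + BCFA[c] + ATP[c] -> TZEAX[c] + ADP[c] + Pi[c] + H2O[c]",
      "TTX_CRUD", "carotenoids", "carotenoid acyltransferase"),
    # biomass: thermophile-style reduced composition (4 amino acids, BCFA
    # membrane lipid, carotenoid) plus GAM ATP hydrolysis
    r("BIOMASS",
      paste("1.861 L_LEU[c] + 1.329 L_VAL[c] + 1.063 L_ILE[c] + 1.063 L_GLU[c]",
            "+ 0.891 BCFA[c] + 0.033 TZEAX[c] + 58.34 ATP[c] + 58.34 H2O[c]",
            "-> 58.34 ADP[c] + 58.34 Pi[c] + 58.34 H[c]"),
      "", "biomass", "biomass equation", obj = 1)
  )
}

fixtureFormulas <- function() c(
  "GLC[e]" = "C6H12O6", "GLC[c]" = "C6H12O6",
  "TRE[e]" = "C12H22O11", "TRE[c]" = "C12H22O11",
  "O2[e]" = "O2", "O2[c]" = "O2",
  "NH4[e]" = "H4N", "NH4[c]" = "H4N",
  "H2O[e]" = "H2O", "H2O[c]" = "H2O",
  "H[e]" = "H", "H[c]" = "H",
  "CO2[e]" = "CO2", "CO2[c]" = "CO2",
  # ionized forms so that ATP hydrolysis balances H and O exactly
  "ATP[c]" = "C10H12N5O13P3", "ADP[c]" = "C10H12N5O10P2", "Pi[c]" = "HO4P",
  "L_LEU[e]" = "C6H13NO2", "L_LEU[c]" = "C6H13NO2",
  "L_VAL[e]" = "C5H11NO2", "L_VAL[c]" = "C5H11NO2",
  "L_ILE[e]" = "C6H13NO2", "L_ILE[c]" = "C6H13NO2",
  "L_GLU[e]" = "C5H9NO4", "L_GLU[c]" = "C5H9NO4")

#' Build the thermophile-like test fixture
#'
#' Returns a deterministic, version-pinned ~40-reaction model emulating the
#' hallmarks of a thermophilic bacterium's metabolism (see the package
#' vignette), together with a glucose-minimal (DMM-like) medium, a complex
#' (TM-like) medium supplying trehalose, branched-chain amino acids and
#' glutamate, and a synthetic-but-realistic thermophile biomass composition
#' table. The fixture is constructed so that growth in the complex medium
#' clearly exceeds the minimal medium, every carotenoid-chain gene is
#' essential in both media, and amino-acid biosynthesis genes are essential
#' only in the minimal medium.
#'
#' @param ngam default NGAM maintenance requirement recorded alongside the
#'   media (mmol gDCW^-1 h^-1).
#' @return list with elements `model`, `dmm`, `tm`, `composition`, `ngam`.
#' @export
buildThermophileFixture <- function(ngam = 14) {
  model <- metabolicModel(fixtureReactionTable(), formulas = fixtureFormulas())
  minerals <- c("EX_NH4", "EX_H2O", "EX_H", "EX_CO2")
  dmm <- mediumSpec("DMM",
                    list(EX_GLC = c(-2, 1000), EX_O2 = c(-10, 1000)),
                    minerals)
  tm <- mediumSpec("TM",
                   list(EX_GLC = c(-2, 1000), EX_O2 = c(-10, 1000),
                        EX_TRE = c(-2, 1000),
                        EX_LEU = c(-2, 1000), EX_VAL = c(-1, 1000),
                        EX_ILE = c(-1, 1000), EX_GLU = c(-2, 1000)),
                   minerals)
  composition <- compositionTable(
    amino_acid_molpct = c(
      alanine = 9.5, arginine = 5.5, asparagine = 3.5, aspartate = 4.5,
      cysteine = 0.8, glutamate = 6.5, glutamine = 3.5, glycine = 9.0,
      histidine = 1.3, isoleucine = 6.0, leucine = 10.5, lysine = 5.5,
      methionine = 2.0, phenylalanine = 3.5, proline = 6.2, serine = 4.0,
      threonine = 4.0, tryptophan = 1.2, tyrosine = 3.0, valine = 10.0),
    fatty_acid_molpct = c(
      "iso-C15:0" = 35, "anteiso-C15:0" = 10, "iso-C16:0" = 8,
      "iso-C17:0" = 40, "anteiso-C17:1" = 5, "C16:0" = 2),
    macromolecule_mass_fractions = c(
      protein = 0.55, lipid = 0.10, DNA = 0.03, RNA = 0.12,
      cell_wall = 0.15, other = 0.05),
    gc_content = 0.694,
    gam_atp = 58.34)
  list(model = model, dmm = dmm, tm = tm, composition = composition,
       ngam = ngam)
}
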