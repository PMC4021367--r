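# Biomass equation assembly from compositional measurements.
#
# All blocks use residue (polymerized) molecular weights: the water released
# on forming the peptide/phosphodiester/ester bond is subtracted from the
# monomer weight, so that coefficient x residue-MW sums reconstruct the
# polymer mass. Coefficients are linear in the macromolecule mass fraction.

MW_WATER <- 18.02

AA_MW <- c(
  alanine = 89.09,  arginine = 174.20, asparagine = 132.12, aspartate = 133.10,
  cysteine = 121.16, glutamate = 147.13, glutamine = 146.15, glycine = 75.07,
  histidine = 155.15, isoleucine = 131.17, leucine = 131.17, lysine = 146.19,
  methionine = 149.21, phenylalanine = 165.19, proline = 115.13,
  serine = 105.09, threonine = 119.12, tryptophan = 204.23,
  tyrosine = 181.19, valine = 117.15)

AA_MET_ID <- c(
  alanine = "L_ALA[c]", arginine = "L_ARG[c]", asparagine = "L_ASN[c]",
  aspartate = "L_ASP[c]", cysteine = "L_CYS[c]", glutamate = "L_GLU[c]",
  glutamine = "L_GLN[c]", glycine = "L_GLY[c]", histidine = "L_HIS[c]",
  isoleucine = "L_ILE[c]", leucine = "L_LEU[c]", lysine = "L_LYS[c]",
  methionine = "L_MET[c]", phenylalanine = "L_PHE[c]", proline = "L_PRO[c]",
  serine = "L_SER[c]", threonine = "L_THR[c]", tryptophan = "L_TRP[c]",
  tyrosine = "L_TYR[c]", valine = "L_VAL[c]")

# common (branched-chain) fatty acids; free-acid molecular weights
FA_MW <- c(
  "iso-C15:0" = 242.40, "anteiso-C15:0" = 242.40, "iso-C16:0" = 256.42,
  "iso-C17:0" = 270.45, "anteiso-C17:0" = 270.45, "anteiso-C17:1" = 268.43,
  "C14:0" = 228.37, "C16:0" = 256.42, "C16:1" = 254.41, "C18:0" = 284.48,
  "C18:1" = 282.46)

# residue weights of nucleotide monophosphates inside the polymer
DNMP_RESIDUE_MW <- c(dAMP = 313.21, dCMP = 289.18, dGMP = 329.21, dTMP = 304.20)
NMP_RESIDUE_MW  <- c(AMP = 329.21, CMP = 305.18, GMP = 345.21, UMP = 306.17)

#' Assemble a biomass composition table
#'
#' Bundles and validates the measurements a biomass equation is built from:
#' amino-acid and fatty-acid compositions (mol%, each summing to 100),
#' macromolecule mass fractions (g gDCW^-1 summing to 1), genomic GC content
#' and the growth-associated maintenance (GAM) ATP cost.
#'
#' @param amino_acid_molpct named numeric over the 20 proteinogenic amino
#'   acids (lower-case full names), mol%.
#' @param fatty_acid_molpct named numeric over fatty-acid species
#'   (e.g. `"iso-C15:0"`), mol%.
#' @param macromolecule_mass_fractions named numeric with entries `protein`,
#'   `lipid`, `DNA`, `RNA`, `cell_wall`, `other`, g gDCW^-1.
#' @param gc_content genomic G+C fraction in (0, 1).
#' @param gam_atp GAM ATP cost, mmol gDCW^-1.
#' @return a validated list of class `"CompositionTable"`.
#' @export
compositionTable <- function(amino_acid_molpct, fatty_acid_molpct,
                             macromolecule_mass_fractions, gc_content,
                             gam_atp) {
  if (abs(sum(amino_acid_molpct) - 100) > 0.1)
    stop("amino-acid mol% must sum to 100 (got ", sum(amino_acid_molpct), ")")
  if (abs(sum(fatty_acid_molpct) - 100) > 0.1)
    stop("fatty-acid mol% must sum to 100 (got ", sum(fatty_acid_molpct), ")")
  if (abs(sum(macromolecule_mass_fractions) - 1) > 1e-3)
    stop("macromolecule mass fractions must sum to 1")
  if (gc_content <= 0 || gc_content >= 1)
    stop("gc_content must lie strictly between 0 and 1")
  if (gam_atp < 0) stop("gam_atp must be non-negative")
  structure(list(amino_acid_molpct = amino_acid_molpct,
                 fatty_acid_molpct = fatty_acid_molpct,
                 macromolecule_mass_fractions = macromolecule_mass_fractions,
                 gc_content = gc_content, gam_atp = gam_atp),
            class = "CompositionTable")
}

#' Amino-acid biomass coefficients from composition
#'
#' Converts a protein amino-acid composition (mol%) and the protein mass
#' fraction into per-amino-acid demands in mmol gDCW^-1, using residue
#' weights (monomer MW minus one water of peptide-bond formation):
#' coeff_a = P * 1000 * f_a / sum_b f_b (MW_b - MW_water).
#'
#' @param molpct named numeric, mol% over amino acids (sums to 100).
#' @param proteinMassFraction protein content, g gDCW^-1.
#' @param mw molecular weight table; defaults to the built-in free-acid
#'   weights, extendable for unusual residues.
#' @return named numeric, mmol gDCW^-1.
#' @examples
#' aminoAcidCoefficients(c(glycine = 100), 0.5)  # 8.764 mmol/gDCW
#' @export
aminoAcidCoefficients <- function(molpct, proteinMassFraction, mw = AA_MW) {
  unknown <- setdiff(names(molpct), names(mw))
  if (length(unknown)) stop("unknown amino acid: ", paste(unknown, collapse = ", "))
  f <- molpct / sum(molpct)
  denom <- sum(f * (mw[names(f)] - MW_WATER))
  stats::setNames(proteinMassFraction * 1000 * as.numeric(f) / denom, names(f))
}

#' Fatty-acid biomass coefficients from composition
#'
#' Same residue-weight scheme as [aminoAcidCoefficients()]: the ester-bond
#' water is subtracted once per acyl chain.
#'
#' @param molpct named numeric, mol% over fatty-acid species (sums to 100).
#' @param lipidMassFraction lipid content, g gDCW^-1.
#' @param mw molecular weight table; defaults to built-in free-acid weights.
#' @return named numeric, mmol gDCW^-1.
#' @export
fattyAcidCoefficients <- function(molpct, lipidMassFraction, mw = FA_MW) {
  unknown <- setdiff(names(molpct), names(mw))
  if (length(unknown)) stop("unknown fatty acid: ", paste(unknown, collapse = ", "))
  f <- molpct / sum(molpct)
  denom <- sum(f * (mw[names(f)] - MW_WATER))
  stats::setNames(lipidMassFraction * 1000 * as.numeric(f) / denom, names(f))
}

#' Nucleotide biomass coefficients from GC content
#'
#' DNA base mole fractions follow directly from the genomic G+C content:
#' dG = dC = gc/2 and dA = dT = (1-gc)/2. RNA defaults to the same split
#' (G = C = gc/2, A = U = (1-gc)/2) unless a measured RNA base composition
#' is supplied. Mass-to-mole conversion uses phosphodiester residue weights.
#'
#' @param gcContent G+C fraction, strictly in (0, 1).
#' @param dnaMassFraction,rnaMassFraction g gDCW^-1.
#' @param rnaFractions optional named numeric (`AMP`, `CMP`, `GMP`, `UMP`)
#'   mole fractions overriding the GC rule for RNA.
#' @return list with named numeric vectors `dna` (dAMP/dCMP/dGMP/dTMP) and
#'   `rna` (AMP/CMP/GMP/UMP), mmol gDCW^-1.
#' @export
nucleotideCoefficients <- function(gcContent, dnaMassFraction, rnaMassFraction,
                                   rnaFractions = NULL) {
  if (gcContent <= 0 || gcContent >= 1)
    stop("gcContent must lie strictly between 0 and 1")
  dfrac <- c(dAMP = (1 - gcContent) / 2, dCMP = gcContent / 2,
             dGMP = gcContent / 2, dTMP = (1 - gcContent) / 2)
  if (is.null(rnaFractions)) {
    rfrac <- c(AMP = (1 - gcContent) / 2, CMP = gcContent / 2,
               GMP = gcContent / 2, UMP = (1 - gcContent) / 2)
  } else {
    rfrac <- rnaFractions / sum(rnaFractions)
    if (!setequal(names(rfrac), names(NMP_RESIDUE_MW)))
      stop("rnaFractions must be named AMP/CMP/GMP/UMP")
    rfrac <- rfrac[names(NMP_RESIDUE_MW)]
  }
  toCoef <- function(frac, mass, mw)
    stats::setNames(mass * 1000 * as.numeric(frac) / sum(frac * mw[names(frac)]),
                    names(frac))
  list(dna = toCoef(dfrac, dnaMassFraction, DNMP_RESIDUE_MW),
       rna = toCoef(rfrac, rnaMassFraction, NMP_RESIDUE_MW))
}

#' Assemble the biomass equation
#'
#' Merges the amino-acid, fatty-acid and nucleotide coefficient blocks into
#' one biomass pseudo-reaction in mmol gDCW^-1, maps component keys to
#' metabolite ids, adds the cell-wall and soluble-pool mass fractions as
#' lumped precursors (nominal residue weight 1000 g/mol), and appends the
#' GAM ATP hydrolysis (ATP + H2O -> ADP + Pi + H at `gam_atp`). The
#' reconstructed dry mass (sum of coefficient x residue weight) must match
#' the summed macromolecule fractions within 1%, otherwise assembly aborts
#' reporting the gap.
#'
#' @param table a `CompositionTable` from [compositionTable()].
#' @param id reaction id for the biomass equation.
#' @param metIds optional named character remapping component keys (amino
#'   acid names, fatty-acid species, dAMP/AMP/...) to metabolite ids.
#' @return a [BiomassEquation-class].
#' @export
assembleBiomass <- function(table, id = "BIOMASS", metIds = NULL) {
  stopifnot(inherits(table, "CompositionTable"))
  mf <- table$macromolecule_mass_fractions
  aa <- aminoAcidCoefficients(table$amino_acid_molpct, mf[["protein"]])
  fa <- fattyAcidCoefficients(table$fatty_acid_molpct, mf[["lipid"]])
  nt <- nucleotideCoefficients(table$gc_content, mf[["DNA"]], mf[["RNA"]])

  faId <- function(k) paste0("FA_", gsub("[^A-Za-z0-9]", "_", toupper(k)), "[c]")
  map <- c(AA_MET_ID,
           stats::setNames(vapply(names(fa), faId, character(1)), names(fa)),
           stats::setNames(paste0(toupper(names(nt$dna)), "[c]"), names(nt$dna)),
           stats::setNames(paste0(names(nt$rna), "[c]"), names(nt$rna)),
           cell_wall = "CELLWALL[c]", other = "SOLPOOL[c]")
  if (!is.null(metIds)) map[names(metIds)] <- metIds

  resMW <- c(AA_MW[names(aa)] - MW_WATER,
             FA_MW[names(fa)] - MW_WATER,
             DNMP_RESIDUE_MW[names(nt$dna)],
             NMP_RESIDUE_MW[names(nt$rna)],
             cell_wall = 1000, other = 1000)
  coefs <- c(aa, fa, nt$dna, nt$rna,
             cell_wall = unname(mf[["cell_wall"]]),
             other = unname(mf[["other"]]))
  coefs <- coefs[coefs > 0]

  mass <- sum(coefs * resMW[names(coefs)]) / 1000
  target <- sum(mf)
  if (abs(mass - target) / target > 0.01)
    stop(sprintf("biomass mass closure violated: reconstructed %.4f g vs %.4f g (gap %.2f%%)",
                 mass, target, 100 * abs(mass - target) / target))

  precursors <- stats::setNames(as.numeric(coefs), map[names(coefs)])
  gam <- table$gam_atp
  products <- stats::setNames(numeric(0), character(0))
  if (gam > 0) {
    atp <- c("ATP[c]" = gam, "H2O[c]" = gam)
    precursors <- mergeCoefs(precursors, atp)
    products <- c("ADP[c]" = gam, "Pi[c]" = gam, "H[c]" = gam)
  }
  new("BiomassEquation", precursors = precursors, products = products,
      gam = gam, id = id)
}

mergeCoefs <- function(a, b) {
  ids <- union(names(a), names(b))
  out <- stats::setNames(numeric(length(ids)), ids)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + b
  out
}

setMethod("show", "BiomassEquation", function(object) {
  cat("BiomassEquation '", object@id, "': ", length(object@precursors),
      " precursors, GAM = ", object@gam, " mmol gDCW^-1\n", sep = "")
})

#' Render a biomass equation as a reaction string
#'
#' @param biomass a [BiomassEquation-class].
#' @return a reaction string suitable for [addReaction()].
#' @export
biomassReactionString <- function(biomass) {
  st <- c(-biomass@precursors, biomass@products)
  st <- st[st != 0]
  stoichToString(st, reversible = FALSE)
}

#' Add a biomass equation to a model as its objective
#'
#' @param model a [MetabolicModel-class].
#' @param biomass a [BiomassEquation-class].
#' @return the model with the biomass reaction appended (subsystem
#'   `"biomass"`, objective coefficient 1).
#' @export
addBiomass <- function(model, biomass) {
  addReaction(model, biomass@id, biomassReactionString(biomass),
              name = "biomass equation", subsystem = "biomass", objective = 1)
}

#' Compare two biomass composition tables
#'
#' Signed per-component differences (b minus a) for each compositional
#' block, e.g. to contrast compositions measured at different growth
#' temperatures.
#'
#' @param a,b `CompositionTable` objects with identical key sets.
#' @return list of data.frames (`amino_acids`, `fatty_acids`,
#'   `macromolecules`) with columns `component`, `a`, `b`, `delta`, plus a
#'   `summary` data.frame of aggregate absolute differences.
#' @export
compareCompositions <- function(a, b) {
  stopifnot(inherits(a, "CompositionTable"), inherits(b, "CompositionTable"))
  block <- function(x, y, what) {
    if (!setequal(names(x), names(y)))
      stop("key mismatch in ", what, " block: ",
           paste(union(setdiff(names(x), names(y)),
                       setdiff(names(y), names(x))), collapse = ", "))
    y <- y[names(x)]
    data.frame(component = names(x), a = as.numeric(x), b = as.numeric(y),
               delta = as.numeric(y) - as.numeric(x), stringsAsFactors = FALSE)
  }
  out <- list(
    amino_acids = block(a$amino_acid_molpct, b$amino_acid_molpct, "amino acid"),
    fatty_acids = block(a$fatty_acid_molpct, b$fatty_acid_molpct, "fatty acid"),
    macromolecules = block(a$macromolecule_mass_fractions,
                           b$macromolecule_mass_fractions, "macromolecule"))
  out$summary <- data.frame(
    block = names(out),
    total_abs_delta = vapply(out, function(d) sum(abs(d$delta)), numeric(1)),
    stringsAsFactors = FALSE)
  rownames(out$summary) <- NULL
  out
}
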