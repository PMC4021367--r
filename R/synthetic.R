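# Deterministic synthetic networks with analytically known FBA optima.

# run expr with a locally seeded RNG, restoring global state afterwards
withLocalSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a planted-optimum toy network
#'
#' Builds a model of `nChains` independent substrate-to-precursor pathways.
#' Chain k imports substrate S_k at up to `uptake[k]` mmol gDCW^-1 h^-1,
#' converts it with molar yield `yield[k]` (applied at the first pathway
#' step), and the biomass reaction drains the chain products with
#' coefficients `biomassCoef[k]`. Because the chains are independent, the
#' FBA optimum has the closed form
#' mu* = min_k uptake_k * yield_k / biomassCoef_k, which makes the LP engine
#' quantitatively checkable without external data. Optionally an `or`
#' isozyme is planted on a chain's transporter and an `and` complex on its
#' first conversion step, and pathway steps can be removed to plant gaps.
#'
#' When only `seed` is given, all parameters are drawn deterministically
#' from realistic discrete ranges (the same seed always returns the
#' identical network).
#'
#' @param nChains number of chains.
#' @param uptake,yield,biomassCoef numeric vectors of length `nChains`
#'   (positive; yields rational-valued so the optimum is exact).
#' @param chainLengths pathway lengths (steps per chain).
#' @param orParalog,andComplex logical vectors: plant an isozyme pair on the
#'   transporter / a two-gene complex on the first step of each chain.
#' @param dropSteps optional integer vector of chains whose last pathway
#'   step is removed (planted defects).
#' @param seed integer seed for the randomized variant.
#' @return list with `model` (a [MetabolicModel-class]), `mu` (the analytic
#'   optimum) and `spec` (the parameters used).
#' @export
generatePlantedNetwork <- function(nChains = NULL, uptake = NULL, yield = NULL,
                                   biomassCoef = NULL, chainLengths = NULL,
                                   orParalog = NULL, andComplex = NULL,
                                   dropSteps = integer(0), seed = NULL) {
  withLocalSeed(seed, {
    if (is.null(nChains)) nChains <- sample(1:4, 1)
    if (is.null(uptake)) uptake <- sample(seq(1, 20, by = 0.5), nChains, replace = TRUE)
    if (is.null(yield)) yield <- sample(c(0.25, 0.5, 1, 1.5, 2), nChains, replace = TRUE)
    if (is.null(biomassCoef)) biomassCoef <- sample(c(0.5, 1, 2), nChains, replace = TRUE)
    if (is.null(chainLengths)) chainLengths <- sample(1:3, nChains, replace = TRUE)
    if (is.null(orParalog)) orParalog <- sample(c(TRUE, FALSE), nChains, replace = TRUE)
    if (is.null(andComplex)) andComplex <- sample(c(TRUE, FALSE), nChains, replace = TRUE)
  })
  stopifnot(length(uptake) == nChains, length(yield) == nChains,
            length(biomassCoef) == nChains, length(chainLengths) == nChains)
  if (any(uptake <= 0) || any(yield <= 0) || any(biomassCoef <= 0))
    stop("uptake, yield and biomassCoef must all be positive")

  rows <- list()
  addRow <- function(id, eq, gpr = "", sub = "", lower = NA, upper = NA, obj = 0)
    rows[[length(rows) + 1L]] <<- data.frame(
      id = id, name = id, equation = eq, gpr = gpr, subsystem = sub,
      lower = lower, upper = upper, objective = obj, stringsAsFactors = FALSE)

  bioTerms <- character(nChains)
  for (k in seq_len(nChains)) {
    s_e <- sprintf("S%d[e]", k); s_c <- sprintf("S%d[c]", k)
    addRow(sprintf("EX_S%d", k), paste(s_e, "<=>"), sub = "exchange",
           lower = -uptake[k], upper = 1000)
    tg <- sprintf("G%dT", k)
    if (orParalog[k]) tg <- sprintf("(G%dT or G%dTb)", k, k)
    addRow(sprintf("T%d", k), paste(s_e, "->", s_c), gpr = tg, sub = "transport")
    prev <- s_c
    for (i in seq_len(chainLengths[k])) {
      nxt <- sprintf("P%d_%d[c]", k, i)
      coef <- if (i == 1L) yield[k] else 1
      gg <- sprintf("G%dS%d", k, i)
      if (i == 1L && andComplex[k]) gg <- sprintf("(G%dS%d and G%dS%db)", k, i, k, i)
      eq <- if (coef == 1) paste(prev, "->", nxt)
            else sprintf("%s -> %.15g %s", prev, coef, nxt)
      if (!(k %in% dropSteps && i == chainLengths[k]))
        addRow(sprintf("C%d_%d", k, i), eq, gpr = gg, sub = "amino acid")
      prev <- nxt
    }
    bioTerms[k] <- if (biomassCoef[k] == 1) prev
                   else sprintf("%.15g %s", biomassCoef[k], prev)
  }
  addRow("BIOMASS", paste(paste(bioTerms, collapse = " + "), "->"),
         sub = "biomass", obj = 1)
  model <- metabolicModel(do.call(rbind, rows))
  list(model = model,
       mu = min(uptake * yield / biomassCoef),
       spec = list(nChains = nChains, uptake = uptake, yield = yield,
                   biomassCoef = biomassCoef, chainLengths = chainLengths,
                   orParalog = orParalog, andComplex = andComplex,
                   dropSteps = dropSteps, seed = seed))
}

#' Generate a randomized minimal/complex media pair for the fixture
#'
#' Draws a glucose-minimal-like medium (one carbon source, oxygen, free
#' minerals) and a complex-like medium (adds trehalose and amino acids) with
#' uptake bounds sampled from realistic ranges, deterministically per seed.
#' Every generated pair keeps the thermophile fixture's wild type feasible.
#'
#' @param seed integer seed.
#' @return list with [MediumSpec-class] elements `dmm` and `tm`.
#' @export
generateMediaPair <- function(seed) {
  withLocalSeed(seed, {
    glc <- round(stats::runif(1, 1, 4), 2)
    o2 <- round(stats::runif(1, 8, 15), 2)
    tre <- round(stats::runif(1, 0.5, 3), 2)
    aa <- round(stats::runif(4, 0.5, 3), 2)
    minerals <- c("EX_NH4", "EX_H2O", "EX_H", "EX_CO2")
    dmm <- mediumSpec(sprintf("DMM_seed%d", seed),
                      list(EX_GLC = c(-glc, 1000), EX_O2 = c(-o2, 1000)),
                      minerals)
    tm <- mediumSpec(sprintf("TM_seed%d", seed),
                     list(EX_GLC = c(-glc, 1000), EX_O2 = c(-o2, 1000),
                          EX_TRE = c(-tre, 1000),
                          EX_LEU = c(-aa[1], 1000), EX_VAL = c(-aa[2], 1000),
                          EX_ILE = c(-aa[3], 1000), EX_GLU = c(-aa[4], 1000)),
                     minerals)
    list(dmm = dmm, tm = tm)
  })
}
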