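# Condition comparison: flux/FVA side-by-sides and the amino-acid
# supply-versus-demand accounting.

#' Biosynthetic demand of biomass precursors
#'
#' demand_i = growth rate x biomass coefficient of i, in mmol gDCW^-1 h^-1.
#'
#' @param biomass a [BiomassEquation-class].
#' @param growthRate specific growth rate mu, h^-1 (>= 0).
#' @return named numeric of per-precursor demands.
#' @export
biosyntheticDemand <- function(biomass, growthRate) {
  stopifnot(growthRate >= 0)
  growthRate * biomass@precursors
}

#' Amino-acid supply-versus-demand balance
#'
#' For every amino acid, partitions its steady-state fate in an optimal flux
#' distribution: `supply` is net uptake from the medium (positive =
#' consumed, negative = secreted or net-synthesized, following the reporting
#' convention of supply/demand tables), `demand` is growth rate x biomass
#' coefficient, and the net production by all other (non-exchange,
#' non-biomass) reactions is split one-sidedly into `from_others` (positive
#' part) and `to_others` (negative part, i.e. the amino acid feeding other
#' pathways such as branched-chain fatty-acid synthesis). Transport between
#' compartments cancels inside the combined extracellular+cytosolic pool.
#' Steady state makes each row close: supply + from_others = demand +
#' to_others; a residual beyond `tol` raises an accounting error naming the
#' metabolite.
#'
#' @param solution an optimal [FluxSolution-class].
#' @param model the [MetabolicModel-class] the solution came from (with the
#'   medium applied).
#' @param aminoAcids character vector of cytosolic amino-acid metabolite ids;
#'   defaults to all `L_XXX[c]` species present in the model.
#' @param tol row-closure tolerance, mmol gDCW^-1 h^-1.
#' @return data.frame with columns `amino_acid`, `supply`, `secreted`,
#'   `demand`, `to_others`, `from_others`, `residual`, `remark`.
#' @export
aminoAcidBalance <- function(solution, model, aminoAcids = NULL, tol = 1e-3) {
  if (solution@status != "optimal") stop("solution is not optimal")
  if (is.null(aminoAcids)) {
    aminoAcids <- intersect(unname(AA_MET_ID), model@mets$id)
    if (!length(aminoAcids)) stop("no amino-acid metabolites found in model")
  }
  v <- solution@fluxes[model@rxns$id]
  S <- model@S
  ex <- isExchange(model)
  bio <- model@rxns$objective != 0
  if (!any(bio)) stop("model has no biomass (objective) reaction")
  mu <- sum(model@rxns$objective[bio] * v[bio])

  out <- data.frame(amino_acid = aminoAcids, supply = 0, secreted = 0,
                    demand = 0, to_others = 0, from_others = 0, residual = 0,
                    remark = "", stringsAsFactors = FALSE)
  for (k in seq_along(aminoAcids)) {
    base <- sub("\\[[a-z]\\]$", "", aminoAcids[k])
    pool <- intersect(paste0(base, c("[c]", "[e]")), model@mets$id)
    rowsum <- Matrix::colSums(S[pool, , drop = FALSE])
    supply <- sum(rowsum[ex] * v[ex])          # production of the pool by exchanges
    demand <- -sum(rowsum[bio] * v[bio])
    internal <- sum(rowsum[!ex & !bio] * v[!ex & !bio])
    res <- supply + internal - demand
    if (abs(res) > tol)
      stop("amino-acid balance does not close for ", aminoAcids[k],
           " (residual ", format(res, digits = 4), ")")
    out$supply[k] <- supply
    out$secreted[k] <- max(-supply, 0)
    out$demand[k] <- demand
    out$to_others[k] <- max(-internal, 0)
    out$from_others[k] <- max(internal, 0)
    out$residual[k] <- res
    out$remark[k] <-
      if (supply < -tol) "net synthesized, not consumed (secreted or unused)"
      else if (out$to_others[k] > tol) "consumed in excess of demand; feeds other pathways"
      else if (out$from_others[k] > tol) "partly synthesized from other precursors"
      else if (abs(supply - demand) <= tol && demand > tol) "utilized from media as per biosynthetic demand"
      else ""
  }
  attr(out, "growth_rate") <- mu
  out
}

#' Compare flux states between two conditions
#'
#' Tabulates the FBA flux and FVA range of each reaction in two conditions
#' side by side, with the flux difference and a flag for direction changes
#' (a reaction running e.g. towards amination in one medium and deamination
#' in the other).
#'
#' @param a,b lists with elements `solution` (a [FluxSolution-class]) and
#'   optionally `fva` (an [FVAResult-class]) for each condition.
#' @param reactions reaction ids to tabulate.
#' @param tol flux magnitude treated as zero for the sign-flip flag.
#' @return data.frame with per-condition flux and range columns, `delta`
#'   (b minus a) and `direction_change`.
#' @export
compareConditions <- function(a, b, reactions, tol = 1e-6) {
  pick <- function(cond, what, ids) {
    if (what == "flux") {
      fx <- cond$solution@fluxes
      if (!all(ids %in% names(fx))) stop("reaction id missing from solution: ",
                                         setdiff(ids, names(fx))[1])
      fx[ids]
    } else {
      if (is.null(cond$fva)) return(rep(NA_real_, length(ids)))
      rg <- cond$fva@ranges
      j <- match(ids, rg$id)
      if (anyNA(j)) stop("reaction id missing from FVA result: ",
                         ids[is.na(j)][1])
      if (what == "min") rg$min[j] else rg$max[j]
    }
  }
  fa <- pick(a, "flux", reactions); fb <- pick(b, "flux", reactions)
  out <- data.frame(
    id = reactions,
    flux_a = fa, min_a = pick(a, "min", reactions), max_a = pick(a, "max", reactions),
    flux_b = fb, min_b = pick(b, "min", reactions), max_b = pick(b, "max", reactions),
    delta = fb - fa,
    direction_change = (fa > tol & fb < -tol) | (fa < -tol & fb > tol),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
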