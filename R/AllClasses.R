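#' @import methods
#' @importClassesFrom Matrix dgCMatrix
NULL

#' MetabolicModel: a constraint-based metabolic network
#'
#' In-memory representation of a genome-scale (or toy) metabolic model:
#' metabolites with compartments and optional elemental formulas, reactions
#' with flux bounds (mmol gDCW^-1 h^-1), gene-protein-reaction (GPR) Boolean
#' rules, a sparse stoichiometric matrix and linear objective coefficients
#' (normally 1 on the biomass pseudo-reaction, whose flux is the specific
#' growth rate in h^-1).
#'
#' Use [metabolicModel()], [readReactionTable()] or [readSBML()] to construct
#' objects; access contents with [metabolites()], [reactions()], [genes()]
#' and [stoichiometricMatrix()] rather than slots.
#'
#' @slot mets data.frame with columns `id`, `name`, `compartment`, `formula`.
#' @slot rxns data.frame with columns `id`, `name`, `subsystem`, `lower`,
#'   `upper`, `reversible`, `objective`, `gpr`.
#' @slot S sparse stoichiometric matrix, metabolites x reactions; negative
#'   coefficients are substrates.
#' @slot gprs list of parsed GPR trees parallel to the reaction table.
#' @slot genes character vector of locus tags (union of all GPR leaves).
#' @export
setClass("MetabolicModel", representation(
  mets  = "data.frame",
  rxns  = "data.frame",
  S     = "dgCMatrix",
  gprs  = "list",
  genes = "character"
))

setValidity("MetabolicModel", function(object) {
  m <- object@mets; r <- object@rxns
  msgs <- character(0)
  if (anyDuplicated(m$id)) msgs <- c(msgs, "duplicated metabolite ids")
  if (anyDuplicated(r$id)) msgs <- c(msgs, "duplicated reaction ids")
  if (!all(m$compartment %in% c("c", "e")))
    msgs <- c(msgs, "compartments must be 'c' (cytosol) or 'e' (extracellular)")
  if (nrow(object@S) != nrow(m) || ncol(object@S) != nrow(r))
    msgs <- c(msgs, "S dimensions do not match metabolite/reaction tables")
  if (any(r$lower > r$upper + 1e-12))
    msgs <- c(msgs, "reaction lower bound exceeds upper bound")
  if (length(object@gprs) != nrow(r))
    msgs <- c(msgs, "gprs list length does not match reaction count")
  leaves <- unique(unlist(lapply(object@gprs, gprLeaves), use.names = FALSE))
  if (length(leaves) && !all(leaves %in% object@genes))
    msgs <- c(msgs, "GPR leaf not present in gene set")
  if (length(msgs)) msgs else TRUE
})

#' MediumSpec: an environmental condition as exchange-flux bounds
#'
#' Named set of bounds on exchange reactions (mmol gDCW^-1 h^-1; uptake is a
#' negative lower bound) plus a list of exchanges left unconstrained, i.e.
#' opened to (-1000, 1000) -- typically minerals, water and protons.
#'
#' @slot name condition name (e.g. "DMM", "TM").
#' @slot bounds data.frame with columns `id`, `lower`, `upper`.
#' @slot unconstrained character vector of exchange reaction ids.
#' @export
setClass("MediumSpec", representation(
  name = "character",
  bounds = "data.frame",
  unconstrained = "character"
))

setValidity("MediumSpec", function(object) {
  b <- object@bounds
  if (nrow(b) && any(b$lower > b$upper + 1e-12)) "medium lower bound exceeds upper bound" else TRUE
})

#' FluxSolution: the result of one FBA solve
#'
#' @slot status one of "optimal", "infeasible", "unbounded".
#' @slot objective objective value Z (h^-1 for a biomass objective); 0 when
#'   infeasible so downstream growth-ratio logic stays defined.
#' @slot fluxes named numeric flux vector v (mmol gDCW^-1 h^-1; biomass in
#'   h^-1); empty when not optimal.
#' @export
setClass("FluxSolution", representation(
  status = "character",
  objective = "numeric",
  fluxes = "numeric"
))

#' FVAResult: per-reaction flux ranges at a fixed objective value
#'
#' @slot ranges data.frame with columns `id`, `min`, `max`.
#' @slot zObj the objective value the ranges were computed at (NA when the
#'   objective was left unconstrained, as for blocked-reaction detection).
#' @slot statuses character vector of solver statuses per sub-problem.
#' @export
setClass("FVAResult", representation(
  ranges = "data.frame",
  zObj = "numeric",
  statuses = "character"
))

#' BiomassEquation: biomass precursor demands in mmol gDCW^-1
#'
#' One pseudo-reaction draining precursors in measured proportions, including
#' the growth-associated maintenance (GAM) ATP hydrolysis; its flux is the
#' specific growth rate (h^-1).
#'
#' @slot precursors named numeric, mmol consumed per gDCW (positive values).
#' @slot products named numeric, mmol released per gDCW (ADP, Pi, H from GAM).
#' @slot gam ATP cost of polymerization/assembly, mmol gDCW^-1.
#' @slot id reaction id used when the equation is added to a model.
#' @export
setClass("BiomassEquation", representation(
  precursors = "numeric",
  products = "numeric",
  gam = "numeric",
  id = "character"
))

#' DeletionReport: single-gene deletion screen results
#'
#' @slot ratios data.frame: one row per gene, one `ratio_<medium>` column per
#'   medium with growth_ko / growth_wt, plus `gene`.
#' @slot growthWT named numeric, wild-type growth rate per medium.
#' @slot disabled list per gene of reaction ids forced to zero flux.
#' @slot classification character per gene: "completely_essential",
#'   "conditionally_essential" or "non_essential" (filled by
#'   [classifyEssentiality()]).
#' @slot threshold growth-ratio cutoff used for classification.
#' @slot tally data.frame of per-subsystem class counts.
#' @export
setClass("DeletionReport", representation(
  ratios = "data.frame",
  growthWT = "numeric",
  disabled = "list",
  classification = "character",
  threshold = "numeric",
  tally = "data.frame"
))
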