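# Curation support: dead ends, blocked reactions, carbon-source usability.

# enumerate usable reaction directions: list of (substrate ids, product ids)
reactionDirections <- function(model) {
  dirs <- list()
  for (j in seq_len(nrow(model@rxns))) {
    s <- stoichOf(model, j)
    sub <- names(s)[s < 0]; prod <- names(s)[s > 0]
    if (model@rxns$upper[j] > 0)
      dirs[[length(dirs) + 1L]] <- list(rxn = model@rxns$id[j], dir = "fwd",
                                        substrates = sub, products = prod)
    if (model@rxns$lower[j] < 0)
      dirs[[length(dirs) + 1L]] <- list(rxn = model@rxns$id[j], dir = "bwd",
                                        substrates = prod, products = sub)
  }
  dirs
}

#' Detect dead-end metabolites
#'
#' Gap finding in the spirit of GapFind, implemented as solver-free iterative
#' set propagation. A metabolite is *producible* if some usable reaction
#' direction makes it from producible substrates, seeding from directions
#' with no substrates at all (the import direction of exchange reactions);
#' `no_production` lists the metabolites never reached. Symmetrically, a
#' metabolite is *consumable* if some direction consumes it into consumable
#' products, seeding from directions with no products (export); metabolites
#' never drained are `no_consumption`. Either kind of dead end blocks every
#' reaction that depends on it at steady state.
#'
#' @param model a [MetabolicModel-class].
#' @return list with character vectors `no_production` and `no_consumption`.
#' @export
findDeadEnds <- function(model) {
  mets <- model@mets$id
  dirs <- reactionDirections(model)
  propagate <- function(from, to) {
    reached <- character(0)
    repeat {
      added <- FALSE
      for (d in dirs) {
        if (all(d[[from]] %in% reached)) {
          new <- setdiff(d[[to]], reached)
          if (length(new)) { reached <- c(reached, new); added <- TRUE }
        }
      }
      if (!added) break
    }
    reached
  }
  producible <- propagate("substrates", "products")
  consumable <- propagate("products", "substrates")
  list(no_production = setdiff(mets, producible),
       no_consumption = setdiff(mets, consumable))
}

#' Medium with every exchange fully open
#'
#' @param model a [MetabolicModel-class].
#' @return a [MediumSpec-class] opening all exchanges to (-1000, 1000).
#' @export
richMedium <- function(model) {
  mediumSpec("rich", unconstrained = model@rxns$id[isExchange(model)])
}

#' Identify blocked reactions
#'
#' A reaction is blocked when its flux variability range under a fully open
#' (rich) medium, with the objective unconstrained, is exactly zero: no
#' steady-state flux distribution can use it. Blocked reactions are the
#' functional footprint of network gaps.
#'
#' @param model a [MetabolicModel-class].
#' @param medium a rich [MediumSpec-class]; defaults to [richMedium()].
#' @param tol flux magnitude below which a range endpoint counts as zero.
#' @return character vector of blocked reaction ids.
#' @export
findBlockedReactions <- function(model, medium = NULL, tol = 1e-6) {
  if (is.null(medium)) medium <- richMedium(model)
  constrained <- applyMedium(model, medium)
  fva <- runFVA(constrained, fixObjective = FALSE)
  with(fva@ranges, id[abs(min) < tol & abs(max) < tol])
}

#' Test growth on individual carbon sources
#'
#' For each candidate source, opens only that carbon exchange (at uptake rate
#' `uptake`) on top of a carbon-free base medium supplying minerals and
#' oxygen, and asks whether FBA growth exceeds `tol`. Sources whose exchange
#' reaction is missing from the model are reported unusable with a reason --
#' the signature of an assimilatory pathway gap.
#'
#' @param model a [MetabolicModel-class].
#' @param sources character vector of exchange reaction ids, one per carbon
#'   source.
#' @param baseMedium a [MediumSpec-class] with minerals/O2 but no carbon.
#' @param uptake uptake rate allowed for the tested source (mmol gDCW^-1 h^-1).
#' @param ngam maintenance requirement during the test.
#' @param tol growth rate above which the source counts as usable.
#' @return data.frame with columns `source`, `usable`, `growth`, `reason`.
#' @export
checkCarbonSources <- function(model, sources, baseMedium, uptake = 10,
                               ngam = 0, tol = 1e-6) {
  exIds <- model@rxns$id[isExchange(model)]
  out <- data.frame(source = sources, usable = FALSE, growth = 0,
                    reason = "", stringsAsFactors = FALSE)
  for (k in seq_along(sources)) {
    src <- sources[k]
    if (!src %in% exIds) {
      out$reason[k] <- "no exchange reaction in model"
      next
    }
    b <- baseMedium@bounds
    b <- rbind(b, data.frame(id = src, lower = -abs(uptake), upper = 1000,
                             stringsAsFactors = FALSE))
    med <- mediumSpec(paste0(baseMedium@name, "+", src), b,
                      baseMedium@unconstrained)
    sol <- solveFBA(applyMedium(model, med, ngam = ngam))
    mu <- if (sol@status == "optimal") sol@objective else 0
    out$growth[k] <- mu
    out$usable[k] <- mu > tol
    if (!out$usable[k]) out$reason[k] <- "no growth as sole carbon source"
  }
  out
}
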