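# Flux balance analysis and flux variability analysis.

#' Apply a medium specification to a model
#'
#' Sets exchange-reaction bounds to encode an environmental condition:
#' exchanges listed in the medium get the stated bounds, exchanges in its
#' `unconstrained` list are opened to (-1000, 1000), and every other exchange
#' is closed to uptake (lower bound raised to 0; secretion stays possible).
#' Optionally enforces non-growth-associated maintenance (NGAM) as a lower
#' bound on the ATP maintenance reaction.
#'
#' @param model a [MetabolicModel-class].
#' @param medium a [MediumSpec-class].
#' @param ngam ATP maintenance requirement, mmol gDCW^-1 h^-1.
#' @param ngamId id of the maintenance reaction; by default a reaction with id
#'   `NGAM`/`ATPM` or "maintenance" in its name is located.
#' @return the constrained model.
#' @export
applyMedium <- function(model, medium, ngam = 0, ngamId = NULL) {
  stopifnot(is(medium, "MediumSpec"))
  ex <- isExchange(model)
  exIds <- model@rxns$id[ex]
  listed <- unique(c(medium@bounds$id, medium@unconstrained))
  bad <- setdiff(listed, exIds)
  if (length(bad))
    stop("medium refers to non-exchange or unknown reaction(s): ",
         paste(bad, collapse = ", "))
  # default: closed medium (no uptake, secretion allowed)
  close_ids <- setdiff(exIds, listed)
  j <- match(close_ids, model@rxns$id)
  model@rxns$lower[j] <- pmax(model@rxns$lower[j], 0)
  if (nrow(medium@bounds)) {
    j <- match(medium@bounds$id, model@rxns$id)
    model@rxns$lower[j] <- medium@bounds$lower
    model@rxns$upper[j] <- medium@bounds$upper
  }
  if (length(medium@unconstrained)) {
    j <- match(medium@unconstrained, model@rxns$id)
    model@rxns$lower[j] <- -1000
    model@rxns$upper[j] <- 1000
  }
  if (ngam > 0) {
    if (is.null(ngamId)) {
      hit <- which(model@rxns$id %in% c("NGAM", "ATPM") |
                     grepl("maintenance", model@rxns$name, ignore.case = TRUE))
      if (!length(hit)) stop("ngam > 0 but no ATP maintenance reaction found")
      ngamId <- model@rxns$id[hit[1]]
    }
    j <- match(ngamId, model@rxns$id)
    if (is.na(j)) stop("unknown NGAM reaction id: ", ngamId)
    model@rxns$lower[j] <- ngam
    model@rxns$upper[j] <- max(model@rxns$upper[j], ngam)
  }
  model
}

#' Flux balance analysis
#'
#' Maximises the linear objective Z = sum_j c_j v_j subject to steady state
#' (sum_j S_ij v_j = 0 for every metabolite i) and capacity bounds
#' (v_j^min <= v_j <= v_j^max), returning one optimal vertex of the flux
#' polytope. An infeasible problem (e.g. an NGAM floor that the medium cannot
#' support) is reported with objective 0 so that downstream growth-ratio
#' logic remains defined; an unbounded objective signals a missing exchange
#' closure.
#'
#' @param model a [MetabolicModel-class] with the medium already applied.
#' @return a [FluxSolution-class].
#' @export
solveFBA <- function(model) {
  r <- model@rxns
  if (all(r$objective == 0)) stop("model has no objective reaction")
  sol <- simplexLP(r$objective, model@S, rep(0, nrow(model@mets)),
                   r$lower, r$upper, maximize = TRUE)
  if (sol$status != "optimal")
    return(new("FluxSolution", status = sol$status, objective = 0,
               fluxes = stats::setNames(numeric(0), character(0))))
  new("FluxSolution", status = "optimal", objective = sol$objective,
      fluxes = stats::setNames(sol$x, r$id))
}

#' @rdname FluxSolution-class
#' @export
setMethod("fluxes", "FluxSolution", function(x) x@fluxes)

#' @rdname FluxSolution-class
#' @export
setMethod("objectiveValue", "FluxSolution", function(x) x@objective)

#' @rdname FluxSolution-class
#' @export
setMethod("solutionStatus", "FluxSolution", function(x) x@status)

setMethod("show", "FluxSolution", function(object) {
  cat("FluxSolution:", object@status)
  if (object@status == "optimal")
    cat(", Z =", format(object@objective, digits = 6))
  cat("\n")
})

#' Flux variability analysis
#'
#' For each reaction, minimises and maximises its flux subject to steady
#' state, the capacity bounds, and the objective fixed at `zObj` (the FBA
#' optimum by default). The objective is held at `fraction * zObj` up to
#' `zObj`, with an additional 1e-9 relative slack for numerical safety; with
#' the default `fraction = 1` this is the fixed-optimum formulation. Setting
#' `fixObjective = FALSE` drops the objective constraint entirely (used for
#' blocked-reaction detection).
#'
#' @param model a [MetabolicModel-class] with medium applied.
#' @param reactions reaction ids to analyse (default: all).
#' @param zObj objective value to fix; computed by [solveFBA()] when NULL.
#' @param fraction fraction of the optimum the objective must retain.
#' @param fixObjective logical; keep the objective constraint?
#' @return an [FVAResult-class].
#' @export
runFVA <- function(model, reactions = NULL, zObj = NULL, fraction = 1.0,
                   fixObjective = TRUE) {
  r <- model@rxns
  if (is.null(reactions)) reactions <- r$id
  j_set <- match(reactions, r$id)
  if (anyNA(j_set)) stop("unknown reaction id: ", reactions[is.na(j_set)][1])
  n <- nrow(r); m <- nrow(model@mets)
  A <- as.matrix(model@S)
  lb <- r$lower; ub <- r$upper
  if (fixObjective) {
    if (is.null(zObj)) {
      fba <- solveFBA(model)
      if (fba@status != "optimal")
        stop("cannot fix objective: FBA status is ", fba@status)
      zObj <- fba@objective
    }
    slack_lo <- fraction * zObj - abs(zObj) * 1e-9 - 1e-9
    slack_hi <- zObj + abs(zObj) * 1e-9 + 1e-9
    A <- rbind(cbind(A, 0), c(r$objective, -1))
    lb <- c(lb, slack_lo); ub <- c(ub, slack_hi)
    b <- rep(0, m + 1)
  } else {
    zObj <- NA_real_
    b <- rep(0, m)
  }
  nv <- length(lb)
  lo <- hi <- numeric(length(j_set))
  statuses <- character(0)
  for (k in seq_along(j_set)) {
    e <- numeric(nv); e[j_set[k]] <- 1
    smin <- simplexLP(e, A, b, lb, ub, maximize = FALSE)
    smax <- simplexLP(e, A, b, lb, ub, maximize = TRUE)
    if (smin$status != "optimal" || smax$status != "optimal")
      stop("FVA sub-problem ", r$id[j_set[k]], " not optimal (",
           smin$status, "/", smax$status,
           "); consider a small relative objective slack")
    lo[k] <- smin$objective; hi[k] <- smax$objective
    statuses <- c(statuses, smin$status, smax$status)
  }
  new("FVAResult",
      ranges = data.frame(id = r$id[j_set], min = lo, max = hi,
                          stringsAsFactors = FALSE),
      zObj = zObj, statuses = statuses)
}

setMethod("show", "FVAResult", function(object) {
  cat("FVAResult:", nrow(object@ranges), "reactions")
  if (!is.na(object@zObj)) cat(", Z fixed at", format(object@zObj, digits = 6))
  cat("\n")
})
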