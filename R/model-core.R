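# Core model container: construction, accessors, element balancing, units.

#' Construct a MetabolicModel from a reaction table
#'
#' The central constructor. Each row of `table` defines one reaction through a
#' reaction string (see [parseReactionString()]); metabolites are collected
#' from the strings, with the compartment parsed from the bracket suffix
#' (`"GLC[e]"` is extracellular, `"PYR[c]"` cytosolic). Blank bounds default
#' to (-1000, 1000) for reversible (`<=>`) and (0, 1000) for irreversible
#' (`->`) reactions, the conventional effectively-unbounded sentinels in
#' mmol gDCW^-1 h^-1.
#'
#' @param table data.frame with columns `id`, `name`, `equation`, `gpr`,
#'   `subsystem`, `lower`, `upper` and optionally `objective` (bounds and
#'   objective may be NA/missing).
#' @param formulas optional named character vector of elemental formulas,
#'   names are metabolite ids (e.g. `c("GLC[c]" = "C6H12O6")`).
#' @param metNames optional named character vector of metabolite display names.
#' @param objective optional reaction id (or named numeric vector of
#'   coefficients) overriding the `objective` column.
#' @return a [MetabolicModel-class] object.
#' @examples
#' m <- metabolicModel(data.frame(
#'   id = c("EX_A", "T_A", "GROWTH"),
#'   name = c("A exchange", "A transport", "biomass"),
#'   equation = c("A[e] <=>", "A[e] -> A[c]", "A[c] ->"),
#'   gpr = c("", "g1", ""),
#'   subsystem = c("exchange", "transport", "biomass"),
#'   lower = c(-10, NA, NA), upper = c(1000, NA, NA)), objective = "GROWTH")
#' solveFBA(m)
#' @export
metabolicModel <- function(table, formulas = NULL, metNames = NULL, objective = NULL) {
  stopifnot(is.data.frame(table), all(c("id", "equation") %in% names(table)))
  n <- nrow(table)
  get_col <- function(col, default) {
    if (col %in% names(table)) {
      v <- table[[col]]
      if (is.factor(v)) v <- as.character(v)
      v
    } else rep(default, n)
  }
  id <- as.character(table$id)
  if (anyDuplicated(id)) stop("duplicated reaction id: ", id[duplicated(id)][1])
  name <- get_col("name", "")
  gpr_str <- get_col("gpr", "")
  gpr_str[is.na(gpr_str)] <- ""
  subsystem <- get_col("subsystem", "")
  subsystem[is.na(subsystem)] <- ""
  lower <- suppressWarnings(as.numeric(get_col("lower", NA_real_)))
  upper <- suppressWarnings(as.numeric(get_col("upper", NA_real_)))
  objcol <- suppressWarnings(as.numeric(get_col("objective", 0)))
  objcol[is.na(objcol)] <- 0

  parsed <- vector("list", n)
  reversible <- logical(n)
  for (j in seq_len(n)) {
    p <- tryCatch(parseReactionString(table$equation[j]),
                  error = function(e) stop("reaction ", id[j], ": ", conditionMessage(e), call. = FALSE))
    parsed[[j]] <- p$stoichiometry
    reversible[j] <- p$reversible
  }
  lower <- ifelse(is.na(lower), ifelse(reversible, -1000, 0), lower)
  upper <- ifelse(is.na(upper), 1000, upper)
  if (any(lower > upper)) stop("lower bound exceeds upper bound for reaction ",
                               id[which(lower > upper)[1]])

  met_ids <- unique(unlist(lapply(parsed, names), use.names = FALSE))
  comp <- sub("^.*\\[([a-z])\\]$", "\\1", met_ids)
  if (any(comp == met_ids))
    stop("metabolite id lacks a [c]/[e] compartment suffix: ",
         met_ids[comp == met_ids][1])
  mets <- data.frame(
    id = met_ids,
    name = if (is.null(metNames)) met_ids else
      ifelse(met_ids %in% names(metNames), metNames[met_ids], met_ids),
    compartment = comp,
    formula = if (is.null(formulas)) "" else
      ifelse(met_ids %in% names(formulas), formulas[met_ids], ""),
    stringsAsFactors = FALSE
  )
  rownames(mets) <- NULL

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  midx <- seq_along(met_ids); names(midx) <- met_ids
  for (j in seq_len(n)) {
    s <- parsed[[j]]
    ii <- c(ii, midx[names(s)])
    jj <- c(jj, rep(j, length(s)))
    xx <- c(xx, unname(s))
  }
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(length(met_ids), n),
                            dimnames = list(met_ids, id))

  gprs <- lapply(gpr_str, parseGpr)
  names(gprs) <- id
  gene_set <- sort(unique(unlist(lapply(gprs, gprLeaves), use.names = FALSE)))
  # canonical string form so round-trips are exact
  gpr_str <- vapply(gprs, gprToString, character(1))

  rxns <- data.frame(id = id, name = name, subsystem = subsystem,
                     lower = lower, upper = upper, reversible = reversible,
                     objective = objcol, gpr = gpr_str,
                     stringsAsFactors = FALSE)
  rownames(rxns) <- NULL
  mod <- new("MetabolicModel", mets = mets, rxns = rxns,
             S = methods::as(methods::as(S, "CsparseMatrix"), "generalMatrix"),
             gprs = gprs, genes = gene_set)
  if (!is.null(objective)) mod <- setObjective(mod, objective)
  mod
}

#' @rdname MetabolicModel-class
#' @export
setMethod("metabolites", "MetabolicModel", function(x) x@mets)

#' @rdname MetabolicModel-class
#' @export
setMethod("reactions", "MetabolicModel", function(x) x@rxns)

#' @rdname MetabolicModel-class
#' @export
setMethod("genes", "MetabolicModel", function(x) x@genes)

#' @rdname MetabolicModel-class
#' @export
setMethod("stoichiometricMatrix", "MetabolicModel", function(x) x@S)

setMethod("show", "MetabolicModel", function(object) {
  cat("MetabolicModel:", nrow(object@mets), "metabolites,",
      nrow(object@rxns), "reactions,", length(object@genes), "genes\n")
  obj <- object@rxns$id[object@rxns$objective != 0]
  if (length(obj)) cat("  objective:", paste(obj, collapse = ", "), "\n")
  nex <- sum(isExchange(object))
  cat("  exchanges:", nex, " subsystems:",
      length(setdiff(unique(object@rxns$subsystem), "")), "\n")
})

#' Identify exchange pseudo-reactions
#'
#' An exchange reaction connects one extracellular species to the environment
#' (`"GLC[e] <=>"`); its bounds encode the medium. Recognised by the `EX_` id
#' prefix or by single-metabolite, one-sided stoichiometry on an
#' extracellular species.
#'
#' @param model a [MetabolicModel-class].
#' @return logical vector along the reaction table.
#' @export
isExchange <- function(model) {
  S <- model@S
  nmet <- Matrix::colSums(S != 0)
  single_e <- rep(FALSE, ncol(S))
  one <- which(nmet == 1L)
  if (length(one)) {
    metrow <- vapply(one, function(j) which(S[, j] != 0), integer(1))
    single_e[one] <- model@mets$compartment[metrow] == "e"
  }
  startsWith(model@rxns$id, "EX_") | single_e
}

#' Adjust flux bounds of a reaction
#'
#' @param model a [MetabolicModel-class].
#' @param id reaction id.
#' @param lower,upper new bounds (NULL keeps the current value).
#' @return the modified model.
#' @export
setBounds <- function(model, id, lower = NULL, upper = NULL) {
  j <- match(id, model@rxns$id)
  if (anyNA(j)) stop("unknown reaction id: ", paste(id[is.na(j)], collapse = ", "))
  if (!is.null(lower)) model@rxns$lower[j] <- lower
  if (!is.null(upper)) model@rxns$upper[j] <- upper
  if (any(model@rxns$lower[j] > model@rxns$upper[j]))
    stop("lower bound exceeds upper bound for ", id[1])
  model
}

#' Set the linear objective
#'
#' @param model a [MetabolicModel-class].
#' @param objective a reaction id (coefficient 1 there, 0 elsewhere) or a
#'   named numeric vector of coefficients.
#' @return the modified model.
#' @export
setObjective <- function(model, objective) {
  coef <- rep(0, nrow(model@rxns))
  if (is.character(objective)) {
    j <- match(objective, model@rxns$id)
    if (anyNA(j)) stop("unknown objective reaction: ", objective[is.na(j)][1])
    coef[j] <- 1
  } else {
    j <- match(names(objective), model@rxns$id)
    if (anyNA(j)) stop("unknown objective reaction: ", names(objective)[is.na(j)][1])
    coef[j] <- unname(objective)
  }
  model@rxns$objective <- coef
  model
}

#' Add or remove a reaction
#'
#' `addReaction` parses a reaction string and appends it (new metabolites are
#' created as needed); `removeReaction` drops reactions and any metabolites
#' left orphaned. Useful for testing candidate gap repairs.
#'
#' @param model a [MetabolicModel-class].
#' @param id reaction id.
#' @param equation reaction string, e.g. `"TRE[c] + H2O[c] -> 2 GLC[c]"`.
#' @param name,gpr,subsystem metadata for the new reaction.
#' @param lower,upper bounds; defaults follow the arrow as in
#'   [metabolicModel()].
#' @param objective objective coefficient of the new reaction.
#' @return the modified model.
#' @export
addReaction <- function(model, id, equation, name = "", gpr = "",
                        subsystem = "", lower = NA, upper = NA, objective = 0) {
  tab <- reactionTableOf(model)
  tab <- rbind(tab, data.frame(id = id, name = name, equation = equation,
                               gpr = gpr, subsystem = subsystem,
                               lower = lower, upper = upper,
                               objective = objective, stringsAsFactors = FALSE))
  fl <- model@mets$formula; names(fl) <- model@mets$id
  nm <- model@mets$name; names(nm) <- model@mets$id
  metabolicModel(tab, formulas = fl[nzchar(fl)], metNames = nm)
}

#' @rdname addReaction
#' @export
removeReaction <- function(model, id) {
  keep <- !(model@rxns$id %in% id)
  if (sum(!keep) != length(unique(id))) stop("unknown reaction id in removal set")
  tab <- reactionTableOf(model)[keep, , drop = FALSE]
  fl <- model@mets$formula; names(fl) <- model@mets$id
  metabolicModel(tab, formulas = fl[nzchar(fl)])
}

# model -> the 8-column reaction table (inverse of metabolicModel())
reactionTableOf <- function(model) {
  r <- model@rxns
  eq <- vapply(seq_len(nrow(r)), function(j)
    stoichToString(stoichOf(model, j), r$reversible[j]), character(1))
  data.frame(id = r$id, name = r$name, equation = eq, gpr = r$gpr,
             subsystem = r$subsystem, lower = r$lower, upper = r$upper,
             objective = r$objective, stringsAsFactors = FALSE)
}

stoichOf <- function(model, j) {
  col <- model@S[, j]
  col <- col[col != 0]
  stats::setNames(as.numeric(col), names(col))
}

#' Parse an elemental formula
#'
#' @param formula string such as `"C6H12O6"`.
#' @return named integer-ish numeric vector of element counts.
#' @export
parseFormula <- function(formula) {
  if (is.na(formula) || !nzchar(formula)) return(stats::setNames(numeric(0), character(0)))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (!length(parts) || paste(parts, collapse = "") != formula)
    stop("malformed formula: ", formula)
  el <- sub("[0-9]*$", "", parts)
  ct <- as.numeric(ifelse(grepl("[0-9]$", parts), sub("^[A-Za-z]+", "", parts), "1"))
  if (any(ct < 0)) stop("negative element count in formula")
  tapply(ct, el, sum)[unique(el)]
}

#' Check elemental balance of internal reactions
#'
#' Sums coefficient x element-count over each reaction's metabolites. A
#' reaction is flagged `imbalanced` iff some element's sum is nonzero (beyond
#' 1e-6); reactions involving any metabolite without a formula are reported
#' `unchecked`, and exchange and biomass pseudo-reactions are `exempt` (they
#' are deliberately one-sided).
#'
#' @param model a [MetabolicModel-class].
#' @return data.frame with columns `id`, `status` and `imbalance` (e.g.
#'   `"C:-3"` for a three-carbon deficit).
#' @export
checkMassBalance <- function(model) {
  ex <- isExchange(model)
  bio <- model@rxns$objective != 0 | model@rxns$subsystem == "biomass"
  fl <- model@mets$formula; names(fl) <- model@mets$id
  out <- data.frame(id = model@rxns$id, status = "balanced", imbalance = "",
                    stringsAsFactors = FALSE)
  for (j in seq_len(nrow(model@rxns))) {
    if (ex[j] || bio[j]) { out$status[j] <- "exempt"; next }
    s <- stoichOf(model, j)
    if (any(!nzchar(fl[names(s)]))) { out$status[j] <- "unchecked"; next }
    tot <- list()
    for (k in seq_along(s)) {
      f <- parseFormula(fl[names(s)[k]])
      for (e in names(f)) tot[[e]] <- (if (is.null(tot[[e]])) 0 else tot[[e]]) + s[k] * f[[e]]
    }
    bad <- names(tot)[vapply(tot, function(v) abs(v) > 1e-6, logical(1))]
    if (length(bad)) {
      out$status[j] <- "imbalanced"
      out$imbalance[j] <- paste(sprintf("%s:%g", bad,
                                        vapply(tot[bad], identity, numeric(1))),
                                collapse = ",")
    }
  }
  out
}

#' Convert optical density to dry cell weight
#'
#' Uses the predetermined linear conversion factor 0.34 g DCW per litre per
#' OD600 unit for Thermus thermophilus cultures.
#'
#' @param od600 optical density at 600 nm (>= 0).
#' @param factor conversion factor, g L^-1 per OD unit.
#' @return dry cell weight concentration, g L^-1.
#' @examples
#' odToDcw(1.0)  # 0.34
#' @export
odToDcw <- function(od600, factor = 0.34) {
  if (any(od600 < 0)) stop("od600 must be non-negative")
  od600 * factor
}

#' Genome ORF coverage of a model
#'
#' @param nGenes number of unique genes in the model.
#' @param nOrfs number of open reading frames in the genome annotation.
#' @return coverage percentage.
#' @export
orfCoverage <- function(nGenes, nOrfs) 100 * nGenes / nOrfs
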