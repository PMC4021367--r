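# Single-gene deletion screening and essentiality classification.

#' Delete a gene via the GPR rules
#'
#' Every reaction whose GPR rule evaluates FALSE with the gene removed (an
#' enzyme complex losing a subunit, or a lone isozyme) has both flux bounds
#' set to zero; all other reactions, including those rescued by an `or`
#' paralog and all non-gene-associated reactions, are untouched.
#'
#' @param model a [MetabolicModel-class].
#' @param gene locus tag(s) to delete; must belong to [genes()] of the model.
#' @return the constrained model, with attribute `"disabled"` listing the
#'   reaction ids forced to zero.
#' @export
deleteGene <- function(model, gene) {
  unknown <- setdiff(gene, model@genes)
  if (length(unknown)) stop("unknown gene: ", paste(unknown, collapse = ", "))
  off <- !vapply(model@gprs, evaluateGpr, logical(1), deleted = gene)
  model@rxns$lower[off] <- 0
  model@rxns$upper[off] <- 0
  attr(model, "disabled") <- model@rxns$id[off]
  model
}

#' Single-gene deletion scan across media
#'
#' For every gene and every medium, applies the medium (with the NGAM
#' maintenance floor), deletes the gene via [deleteGene()], and re-solves
#' FBA. The growth ratio is growth_ko / growth_wt; knockouts whose problem
#' becomes infeasible (the maintenance floor can no longer be met) score
#' ratio 0. Wild-type growth is recomputed per medium.
#'
#' @param model a [MetabolicModel-class] (medium not yet applied).
#' @param media a list of [MediumSpec-class] objects; names default to each
#'   medium's own name.
#' @param ngam NGAM requirement passed to [applyMedium()].
#' @param genes genes to scan (default: all model genes).
#' @return a [DeletionReport-class].
#' @export
scanSingleDeletions <- function(model, media, ngam = 0, genes = NULL) {
  if (is(media, "MediumSpec")) media <- list(media)
  if (is.null(names(media)) || any(!nzchar(names(media))))
    names(media) <- vapply(media, function(m) m@name, character(1))
  if (is.null(genes)) genes <- model@genes
  wt <- numeric(length(media)); names(wt) <- names(media)
  constrained <- vector("list", length(media))
  for (k in seq_along(media)) {
    constrained[[k]] <- applyMedium(model, media[[k]], ngam = ngam)
    sol <- solveFBA(constrained[[k]])
    if (sol@status != "optimal" || sol@objective <= 1e-9)
      stop("wild-type growth is not positive in medium '", names(media)[k],
           "'; check the medium configuration")
    wt[k] <- sol@objective
  }
  ratios <- matrix(NA_real_, nrow = length(genes), ncol = length(media),
                   dimnames = list(genes, names(media)))
  disabled <- vector("list", length(genes)); names(disabled) <- genes
  for (g in seq_along(genes)) {
    for (k in seq_along(media)) {
      ko <- deleteGene(constrained[[k]], genes[g])
      if (k == 1L) disabled[[g]] <- attr(ko, "disabled")
      if (!length(attr(ko, "disabled"))) {   # gene in no GPR: nothing changes
        ratios[g, k] <- 1
        next
      }
      sol <- solveFBA(ko)
      mu <- if (sol@status == "optimal") max(sol@objective, 0) else 0
      ratios[g, k] <- mu / wt[k]
    }
  }
  df <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (k in seq_along(media))
    df[[paste0("ratio_", names(media)[k])]] <- ratios[, k]
  rownames(df) <- NULL
  new("DeletionReport", ratios = df, growthWT = wt, disabled = disabled,
      classification = character(0), threshold = NA_real_,
      tally = data.frame())
}

#' Classify gene essentiality from a deletion report
#'
#' A gene is essential in a medium iff its growth ratio is less than or equal
#' to `threshold` (5% of wild-type by default; the boundary value counts as
#' essential). Genes essential in all media are completely essential, in at
#' least one but not all conditionally essential, and otherwise
#' non-essential. A per-subsystem tally is added, attributing each gene to
#' the subsystems of the reactions its GPR participates in.
#'
#' @param report a [DeletionReport-class] from [scanSingleDeletions()].
#' @param model the [MetabolicModel-class] the scan was run on (for the
#'   subsystem tally; optional).
#' @param threshold growth-ratio cutoff, default 0.05.
#' @return the report with `classification`, `threshold` and `tally` filled.
#' @export
classifyEssentiality <- function(report, model = NULL, threshold = 0.05) {
  rcols <- grep("^ratio_", names(report@ratios))
  ess <- as.matrix(report@ratios[rcols]) <= threshold
  nEss <- rowSums(ess)
  cls <- ifelse(nEss == length(rcols), "completely_essential",
                ifelse(nEss > 0, "conditionally_essential", "non_essential"))
  report@classification <- stats::setNames(cls, report@ratios$gene)
  report@threshold <- threshold
  if (!is.null(model)) {
    subsysOf <- function(g) {
      hit <- vapply(model@gprs, function(t) g %in% gprLeaves(t), logical(1))
      unique(model@rxns$subsystem[hit])
    }
    rows <- list()
    for (g in report@ratios$gene) {
      for (s in subsysOf(g))
        rows[[length(rows) + 1L]] <- data.frame(subsystem = s, gene = g,
                                                class = report@classification[[g]],
                                                stringsAsFactors = FALSE)
    }
    if (length(rows)) {
      long <- do.call(rbind, rows)
      report@tally <- as.data.frame.matrix(table(long$subsystem, long$class))
      report@tally <- cbind(subsystem = rownames(report@tally), report@tally)
      rownames(report@tally) <- NULL
    }
  }
  report
}

setMethod("show", "DeletionReport", function(object) {
  cat("DeletionReport:", nrow(object@ratios), "genes x",
      length(grep("^ratio_", names(object@ratios))), "media\n")
  if (length(object@classification)) {
    tb <- table(object@classification)
    cat(" ", paste(names(tb), tb, sep = ": ", collapse = ", "),
        "(threshold", object@threshold, ")\n")
  }
})
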