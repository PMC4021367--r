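# Reaction-string parsing and tabular (TSV) model io.

#' Parse a reaction string
#'
#' Understands `"substrates -> products"` (irreversible) and
#' `"substrates <=> products"` (reversible) with optional decimal
#' coefficients and bracketed compartments, e.g.
#' `"2 NAD[c] + H2O[c] + L_HISN[c] -> L_HIS[c] + 3 H[c] + 2 NADH[c]"`.
#' The spaced arrow variants `"- >"` and `"< = >"` found in printed reaction
#' tables are accepted; either side may be empty (exchange/sink reactions).
#'
#' @param text reaction string.
#' @return list with `stoichiometry` (named numeric; substrates negative,
#'   products positive) and `reversible` (logical).
#' @examples
#' parseReactionString("L_ASP[c] + AKG[c] < = > L_GLU[c] + OAC[c]")
#' @export
parseReactionString <- function(text) {
  if (is.na(text) || !nzchar(trimws(text))) stop("empty reaction string")
  s <- gsub("<\\s*=\\s*>", "<=>", text)
  s <- gsub("-\\s+>", "->", s)
  rev_arrow <- grepl("<=>", s, fixed = TRUE)
  arrow <- if (rev_arrow) "<=>" else "->"
  parts <- strsplit(s, arrow, fixed = TRUE)[[1]]
  n_arrows <- lengths(regmatches(s, gregexpr(arrow, s, fixed = TRUE)))
  if (!grepl(arrow, s, fixed = TRUE) || n_arrows != 1L)
    stop("reaction string must contain exactly one '->' or '<=>' arrow: ", text)
  lhs <- parseSide(parts[1], text)
  rhs <- if (length(parts) > 1) parseSide(parts[2], text) else numeric(0)
  both <- intersect(names(lhs), names(rhs))
  if (length(both))
    stop("metabolite appears on both sides: ", both[1])
  if (!length(lhs) && !length(rhs))
    stop("reaction string has no metabolites: ", text)
  st <- c(-lhs, rhs)
  list(stoichiometry = st, reversible = rev_arrow)
}

parseSide <- function(side, context) {
  side <- trimws(side)
  if (!nzchar(side)) return(stats::setNames(numeric(0), character(0)))
  toks <- trimws(strsplit(side, "\\s+\\+\\s+")[[1]])
  ids <- character(length(toks)); coefs <- numeric(length(toks))
  for (k in seq_along(toks)) {
    m <- regmatches(toks[k], regexec("^([0-9]*\\.?[0-9]+(?:[eE][+-]?[0-9]+)?)\\s+(.+)$", toks[k]))[[1]]
    if (length(m)) {
      coefs[k] <- as.numeric(m[2]); ids[k] <- m[3]
    } else {
      coefs[k] <- 1; ids[k] <- toks[k]
    }
    if (!nzchar(ids[k]) || grepl("[+[:space:]]", ids[k]))
      stop("malformed term '", toks[k], "' in: ", context)
  }
  if (anyDuplicated(ids))
    stop("metabolite duplicated on one side: ", ids[duplicated(ids)][1])
  stats::setNames(coefs, ids)
}

# inverse of parseReactionString; always emits compact arrows
stoichToString <- function(stoich, reversible) {
  fmt <- function(v) {
    terms <- vapply(seq_along(v), function(k) {
      cf <- abs(v[k])
      if (abs(cf - 1) < 1e-15) names(v)[k]
      else paste(sprintf("%.15g", cf), names(v)[k])
    }, character(1))
    paste(terms, collapse = " + ")
  }
  lhs <- stoich[stoich < 0]; rhs <- stoich[stoich > 0]
  arrow <- if (reversible) "<=>" else "->"
  trimws(paste(fmt(lhs), arrow, fmt(rhs)))
}

#' Read / write a model as a tabular reaction list
#'
#' The TSV has one reaction per row with columns `id`, `name`, `equation`,
#' `gpr`, `subsystem`, `lower`, `upper` and optionally `objective`. Blank
#' bounds take the defaults of [metabolicModel()]; GPR strings use
#' parentheses with `and`/`or` (case-insensitive). When no `objective` column
#' is present, a reaction whose id or name contains "biomass" becomes the
#' objective.
#'
#' @param path file path.
#' @param model a [MetabolicModel-class] (for writing).
#' @return `readReactionTable`: a [MetabolicModel-class];
#'   `writeReactionTable`: the path, invisibly.
#' @export
readReactionTable <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "",
                           na.strings = c("NA", ""))
  need <- c("id", "equation")
  if (!all(need %in% names(tab)))
    stop("reaction table must have at least columns 'id' and 'equation'")
  for (r in seq_len(nrow(tab))) {
    tryCatch(parseReactionString(tab$equation[r]),
             error = function(e) stop("row ", r, ": ", conditionMessage(e),
                                      call. = FALSE))
  }
  mod <- metabolicModel(tab)
  if (!"objective" %in% names(tab) && all(mod@rxns$objective == 0)) {
    hit <- which(grepl("biomass", mod@rxns$id, ignore.case = TRUE) |
                   grepl("biomass", mod@rxns$name, ignore.case = TRUE))
    if (length(hit)) mod <- setObjective(mod, mod@rxns$id[hit[1]])
  }
  mod
}

#' @rdname readReactionTable
#' @export
writeReactionTable <- function(model, path) {
  tab <- reactionTableOf(model)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
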