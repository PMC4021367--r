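# Gene-protein-reaction (GPR) Boolean rules.
#
# A rule is stored as a tree: a leaf is a single locus tag (character scalar),
# an inner node is list(op = "and"|"or", args = list(...)). NULL is the empty
# rule (spontaneous / non-gene-associated reaction) and always evaluates TRUE.

#' Parse a GPR rule string into a Boolean tree
#'
#' Accepts parenthesised expressions over gene locus tags with `and` / `or`
#' connectives (case-insensitive), e.g. `"(TTC0049 or TTC0045)"` for isozymes
#' or `"(A and B)"` for an enzyme complex. An empty or all-whitespace string
#' yields `NULL`, the empty rule.
#'
#' @param text GPR rule string.
#' @return a GPR tree (`NULL`, a character leaf, or a nested list).
#' @examples
#' g <- parseGpr("(TTC0049 or TTC0045)")
#' evaluateGpr(g, deleted = "TTC0049")  # TRUE: isozyme survives
#' @export
parseGpr <- function(text) {
  if (is.null(text) || is.na(text) || !nzchar(trimws(text))) return(NULL)
  toks <- gprTokens(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks; st$pos <- 1L
  tree <- gprParseOr(st)
  if (st$pos <= length(st$toks))
    stop("trailing tokens in GPR rule: ", paste(st$toks[st$pos:length(st$toks)], collapse = " "))
  tree
}

gprTokens <- function(text) {
  text <- gsub("([()])", " \\1 ", text)
  toks <- strsplit(trimws(text), "\\s+")[[1]]
  toks[nzchar(toks)]
}

gprPeek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_

gprParseOr <- function(st) {
  args <- list(gprParseAnd(st))
  while (!is.na(tk <- gprPeek(st)) && tolower(tk) == "or") {
    st$pos <- st$pos + 1L
    args <- c(args, list(gprParseAnd(st)))
  }
  if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
}

gprParseAnd <- function(st) {
  args <- list(gprParseAtom(st))
  while (!is.na(tk <- gprPeek(st)) && tolower(tk) == "and") {
    st$pos <- st$pos + 1L
    args <- c(args, list(gprParseAtom(st)))
  }
  if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
}

gprParseAtom <- function(st) {
  tk <- gprPeek(st)
  if (is.na(tk)) stop("unexpected end of GPR rule")
  if (tk == "(") {
    st$pos <- st$pos + 1L
    inner <- gprParseOr(st)
    if (!identical(gprPeek(st), ")")) stop("unbalanced parenthesis in GPR rule")
    st$pos <- st$pos + 1L
    return(inner)
  }
  if (tk == ")" || tolower(tk) %in% c("and", "or"))
    stop("unexpected token '", tk, "' in GPR rule")
  st$pos <- st$pos + 1L
  tk
}

#' Evaluate a GPR rule under a set of deleted genes
#'
#' A leaf is active iff its gene is not deleted; `and` nodes require all
#' children active (complex loses a subunit otherwise), `or` nodes require at
#' least one (isozymes). The empty rule is always active, so spontaneous
#' reactions are never disabled by gene deletions.
#'
#' @param gpr a GPR tree from [parseGpr()] (or `NULL`).
#' @param deleted character vector of deleted locus tags.
#' @return logical: can the reaction still be catalysed?
#' @export
evaluateGpr <- function(gpr, deleted = character(0)) {
  if (is.null(gpr)) return(TRUE)
  if (is.character(gpr)) return(!(gpr %in% deleted))
  vals <- vapply(gpr$args, evaluateGpr, logical(1), deleted = deleted)
  if (gpr$op == "and") all(vals) else any(vals)
}

#' @rdname parseGpr
#' @param gpr a GPR tree.
#' @return `gprLeaves`: character vector of locus tags in the rule;
#'   `gprToString`: the canonical parenthesised string form.
#' @export
gprLeaves <- function(gpr) {
  if (is.null(gpr)) return(character(0))
  if (is.character(gpr)) return(gpr)
  unique(unlist(lapply(gpr$args, gprLeaves), use.names = FALSE))
}

#' @rdname parseGpr
#' @export
gprToString <- function(gpr) {
  if (is.null(gpr)) return("")
  if (is.character(gpr)) return(gpr)
  parts <- vapply(gpr$args, function(a) {
    s <- gprToString(a)
    if (is.list(a)) paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = paste0(" ", gpr$op, " "))
}
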