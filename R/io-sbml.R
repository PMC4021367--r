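# SBML level 2 version 1 reader/writer.
#
# L2v1 predates the fbc extension, so the COBRA-era plain-text conventions
# are used: flux bounds and objective coefficients live in kineticLaw
# parameters (LOWER_BOUND / UPPER_BOUND / OBJECTIVE_COEFFICIENT) and GPR
# rules and subsystems in html notes lines ("GENE_ASSOCIATION: ...",
# "SUBSYSTEM: ..."). Species ids are mangled as M_<base>_<compartment>
# because SBML SIds cannot contain brackets.

SBML_NS <- "http://www.sbml.org/sbml/level2"

sbmlSpeciesId <- function(metId) {
  base <- sub("\\[([a-z])\\]$", "", metId)
  comp <- sub("^.*\\[([a-z])\\]$", "\\1", metId)
  paste0("M_", gsub("[^A-Za-z0-9_]", "_", base), "_", comp)
}

#' Write a model as SBML level 2 version 1
#'
#' @param model a [MetabolicModel-class].
#' @param path output file.
#' @param id model id used in the document.
#' @return the path, invisibly.
#' @export
writeSBML <- function(model, path, id = "model") {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    gsub('"', "&quot;", x, fixed = TRUE)
  }
  L <- c(sprintf('<?xml version="1.0" encoding="UTF-8"?>'),
         sprintf('<sbml xmlns="%s" level="2" version="1">', SBML_NS),
         sprintf('  <model id="%s" name="%s">', esc(id), esc(id)),
         '    <listOfCompartments>',
         '      <compartment id="c" name="cytosol"/>',
         '      <compartment id="e" name="extracellular"/>',
         '    </listOfCompartments>',
         '    <listOfSpecies>')
  m <- model@mets
  for (i in seq_len(nrow(m))) {
    notes <- if (nzchar(m$formula[i]))
      sprintf(paste0('><notes><body xmlns="http://www.w3.org/1999/xhtml">',
                     '<p>FORMULA: %s</p></body></notes></species>'),
              esc(m$formula[i]))
    else "/>"
    L <- c(L, sprintf('      <species id="%s" name="%s" compartment="%s"%s',
                      sbmlSpeciesId(m$id[i]), esc(m$name[i]),
                      m$compartment[i], notes))
  }
  L <- c(L, '    </listOfSpecies>', '    <listOfReactions>')
  r <- model@rxns
  for (j in seq_len(nrow(r))) {
    s <- stoichOf(model, j)
    L <- c(L, sprintf('      <reaction id="%s" name="%s" reversible="%s">',
                      esc(r$id[j]), esc(r$name[j]),
                      tolower(as.character(r$reversible[j]))))
    L <- c(L, '        <notes><body xmlns="http://www.w3.org/1999/xhtml">',
           sprintf('          <p>GENE_ASSOCIATION: %s</p>', esc(r$gpr[j])),
           sprintf('          <p>SUBSYSTEM: %s</p>', esc(r$subsystem[j])),
           '        </body></notes>')
    sub <- s[s < 0]; prod <- s[s > 0]
    if (length(sub)) {
      L <- c(L, '        <listOfReactants>',
             sprintf('          <speciesReference species="%s" stoichiometry="%.15g"/>',
                     vapply(names(sub), sbmlSpeciesId, character(1)), -unname(sub)),
             '        </listOfReactants>')
    }
    if (length(prod)) {
      L <- c(L, '        <listOfProducts>',
             sprintf('          <speciesReference species="%s" stoichiometry="%.15g"/>',
                     vapply(names(prod), sbmlSpeciesId, character(1)), unname(prod)),
             '        </listOfProducts>')
    }
    L <- c(L, '        <kineticLaw>',
           '          <math xmlns="http://www.w3.org/1998/Math/MathML"><ci> FLUX_VALUE </ci></math>',
           '          <listOfParameters>',
           sprintf('            <parameter id="LOWER_BOUND" value="%.15g" units="mmol_per_gDW_per_hr"/>', r$lower[j]),
           sprintf('            <parameter id="UPPER_BOUND" value="%.15g" units="mmol_per_gDW_per_hr"/>', r$upper[j]),
           sprintf('            <parameter id="OBJECTIVE_COEFFICIENT" value="%.15g"/>', r$objective[j]),
           '          </listOfParameters>',
           '        </kineticLaw>',
           '      </reaction>')
  }
  L <- c(L, '    </listOfReactions>', '  </model>', '</sbml>')
  writeLines(L, path)
  invisible(path)
}

#' Read an SBML level 2 version 1 model
#'
#' Species become metabolites (compartment from the `compartment` attribute,
#' formulas from `FORMULA:` notes lines), reactions take their bounds from
#' kineticLaw parameters (defaults per reversibility when absent) and their
#' GPR from `GENE_ASSOCIATION:` notes lines. The objective is taken from
#' `OBJECTIVE_COEFFICIENT` parameters; if all are zero, a reaction whose id
#' or name contains "biomass" is used, unless `objective` overrides it.
#' Reactions without a GPR note are tolerated (counted in a single warning).
#'
#' @param path SBML file (must be level 2, version 1).
#' @param objective optional reaction id forced as the objective.
#' @return a [MetabolicModel-class].
#' @export
readSBML <- function(path, objective = NULL) {
  doc <- xml2::read_xml(path)
  lev <- xml2::xml_attr(doc, "level"); ver <- xml2::xml_attr(doc, "version")
  if (!identical(lev, "2") || !identical(ver, "1"))
    stop("unsupported SBML dialect: level ", lev, " version ", ver,
         " (need level 2 version 1)")
  xml2::xml_ns_strip(doc)

  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  spId <- xml2::xml_attr(sp, "id")
  spName <- xml2::xml_attr(sp, "name")
  spComp <- xml2::xml_attr(sp, "compartment")
  spNotes <- vapply(sp, function(node) {
    ps <- xml2::xml_find_all(node, ".//notes//p")
    paste(xml2::xml_text(ps), collapse = "\n")
  }, character(1))
  spFormula <- vapply(spNotes, function(t) {
    m <- regmatches(t, regexec("FORMULA:\\s*(\\S+)", t))[[1]]
    if (length(m) >= 2) m[2] else ""
  }, character(1), USE.NAMES = FALSE)
  # M_<base>_<comp> -> <base>[<comp>]
  base <- spId
  pref <- startsWith(base, "M_")
  base[pref] <- substring(base[pref], 3)
  suffix <- paste0("_", spComp)
  hasSuffix <- substring(base, nchar(base) - nchar(suffix) + 1) == suffix
  base[hasSuffix] <- substring(base[hasSuffix], 1,
                               nchar(base[hasSuffix]) - nchar(suffix)[hasSuffix])
  metId <- paste0(base, "[", spComp, "]")
  metMap <- stats::setNames(metId, spId)

  rx <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  n <- length(rx)
  id <- xml2::xml_attr(rx, "id")
  nm <- xml2::xml_attr(rx, "name"); nm[is.na(nm)] <- ""
  revs <- xml2::xml_attr(rx, "reversible")
  revs <- is.na(revs) | tolower(revs) == "true"   # SBML default: reversible
  eq <- character(n); gpr <- character(n); subsys <- character(n)
  lower <- rep(NA_real_, n); upper <- rep(NA_real_, n); objc <- rep(0, n)
  missing_gpr <- 0L
  for (j in seq_len(n)) {
    node <- rx[[j]]
    getSide <- function(xp) {
      refs <- xml2::xml_find_all(node, xp)
      if (!length(refs)) return(numeric(0))
      st <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      st[is.na(st)] <- 1
      ids <- metMap[xml2::xml_attr(refs, "species")]
      if (anyNA(ids)) stop("reaction ", id[j], ": unresolved species reference")
      stats::setNames(st, ids)
    }
    sub <- getSide("./listOfReactants/speciesReference")
    prod <- getSide("./listOfProducts/speciesReference")
    fmt <- function(v) paste(sprintf("%.15g %s", unname(v), names(v)),
                             collapse = " + ")
    eq[j] <- trimws(paste(if (length(sub)) fmt(sub) else "",
                          if (revs[j]) "<=>" else "->",
                          if (length(prod)) fmt(prod) else ""))
    notes <- paste(xml2::xml_text(xml2::xml_find_all(node, "./notes//p")),
                   collapse = "\n")
    g <- regmatches(notes, regexec("GENE_ASSOCIATION:[ \t]*([^\n]*)", notes))[[1]]
    if (length(g) >= 2) gpr[j] <- trimws(g[2]) else missing_gpr <- missing_gpr + 1L
    s <- regmatches(notes, regexec("SUBSYSTEM:[ \t]*([^\n]*)", notes))[[1]]
    if (length(s) >= 2) subsys[j] <- trimws(s[2])
    pars <- xml2::xml_find_all(node, "./kineticLaw/listOfParameters/parameter")
    if (length(pars)) {
      pid <- xml2::xml_attr(pars, "id")
      pval <- as.numeric(xml2::xml_attr(pars, "value"))
      if ("LOWER_BOUND" %in% pid) lower[j] <- pval[match("LOWER_BOUND", pid)]
      if ("UPPER_BOUND" %in% pid) upper[j] <- pval[match("UPPER_BOUND", pid)]
      if ("OBJECTIVE_COEFFICIENT" %in% pid)
        objc[j] <- pval[match("OBJECTIVE_COEFFICIENT", pid)]
    }
  }
  if (missing_gpr > 0L)
    warning(missing_gpr, " reaction(s) without a GENE_ASSOCIATION note; ",
            "empty GPR assumed")
  tab <- data.frame(id = id, name = nm, equation = eq, gpr = gpr,
                    subsystem = subsys, lower = lower, upper = upper,
                    objective = objc, stringsAsFactors = FALSE)
  fl <- stats::setNames(spFormula, metId)
  nms <- stats::setNames(ifelse(is.na(spName), metId, spName), metId)
  mod <- metabolicModel(tab, formulas = fl[nzchar(fl)], metNames = nms)
  if (!is.null(objective)) {
    mod <- setObjective(mod, objective)
  } else if (all(mod@rxns$objective == 0)) {
    hit <- which(grepl("biomass", id, ignore.case = TRUE) |
                   grepl("biomass", nm, ignore.case = TRUE))
    if (length(hit)) mod <- setObjective(mod, id[hit[1]])
  }
  mod
}
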