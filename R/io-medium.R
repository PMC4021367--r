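# Media specifications: constructor and JSON/YAML io.

#' Create a medium specification
#'
#' @param name condition name, e.g. `"DMM"`.
#' @param bounds named list of `c(lower, upper)` exchange bounds (names are
#'   exchange reaction ids; uptake is a negative lower bound) or an
#'   equivalent data.frame with columns `id`, `lower`, `upper`.
#' @param unconstrained exchange ids opened to (-1000, 1000), typically the
#'   mineral/water/proton exchanges.
#' @return a [MediumSpec-class].
#' @examples
#' dmm <- mediumSpec("DMM", bounds = list(EX_GLC = c(-10, 1000),
#'                                        EX_O2 = c(-10, 1000)),
#'                   unconstrained = c("EX_NH4", "EX_H2O", "EX_H"))
#' @export
mediumSpec <- function(name, bounds = list(), unconstrained = character(0)) {
  if (is.data.frame(bounds)) {
    b <- data.frame(id = as.character(bounds$id),
                    lower = as.numeric(bounds$lower),
                    upper = as.numeric(bounds$upper),
                    stringsAsFactors = FALSE)
  } else if (length(bounds)) {
    b <- data.frame(id = names(bounds),
                    lower = vapply(bounds, function(v) v[1], numeric(1)),
                    upper = vapply(bounds, function(v) v[2], numeric(1)),
                    stringsAsFactors = FALSE)
  } else {
    b <- data.frame(id = character(0), lower = numeric(0), upper = numeric(0),
                    stringsAsFactors = FALSE)
  }
  rownames(b) <- NULL
  new("MediumSpec", name = name, bounds = b,
      unconstrained = as.character(unconstrained))
}

setMethod("show", "MediumSpec", function(object) {
  cat("MediumSpec '", object@name, "': ", nrow(object@bounds),
      " bounded exchange(s), ", length(object@unconstrained),
      " unconstrained\n", sep = "")
})

#' Read / write a medium file
#'
#' Media files are JSON or YAML (chosen by file extension) with the schema
#' `{name, bounds: {exchange_id: [lower, upper]}, unconstrained: [ids]}`,
#' bounds in mmol gDCW^-1 h^-1. An empty file yields the closed medium (all
#' exchanges shut to uptake when applied). When `model` is given, exchange
#' ids are validated against it immediately.
#'
#' @param path file path ending in `.json`, `.yml` or `.yaml`.
#' @param model optional [MetabolicModel-class] for id validation.
#' @param medium a [MediumSpec-class] (for writing).
#' @return `readMedium`: a [MediumSpec-class]; `writeMedium`: the path,
#'   invisibly.
#' @export
readMedium <- function(path, model = NULL) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  spec <- if (!nzchar(trimws(txt))) list()
  else if (grepl("\\.json$", path, ignore.case = TRUE)) jsonlite::fromJSON(txt)
  else yaml::yaml.load(txt)
  if (is.null(spec)) spec <- list()
  nm <- if (!is.null(spec$name)) spec$name else
    sub("\\.[^.]+$", "", basename(path))
  bounds <- spec$bounds
  if (is.null(bounds)) bounds <- list()
  bounds <- lapply(bounds, function(v) {
    v <- as.numeric(unlist(v))
    if (length(v) != 2 || anyNA(v) || v[1] > v[2])
      stop("medium bound must be [lower, upper] with lower <= upper")
    v
  })
  unc <- as.character(unlist(spec$unconstrained))
  med <- mediumSpec(nm, bounds, unc)
  if (!is.null(model)) {
    exIds <- model@rxns$id[isExchange(model)]
    bad <- setdiff(c(med@bounds$id, med@unconstrained), exIds)
    if (length(bad))
      stop("medium refers to unknown exchange id(s): ",
           paste(bad, collapse = ", "))
  }
  med
}

#' @rdname readMedium
#' @export
writeMedium <- function(medium, path) {
  b <- medium@bounds
  obj <- list(
    name = medium@name,
    bounds = stats::setNames(lapply(seq_len(nrow(b)),
                                    function(k) c(b$lower[k], b$upper[k])),
                             b$id),
    unconstrained = medium@unconstrained
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    writeLines(yaml::as.yaml(obj), path)
  }
  invisible(path)
}
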