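#' @rdname MetabolicModel-class
#' @param object,x a \code{MetabolicModel} (or other package object).
#' @export
setGeneric("metabolites", function(x) standardGeneric("metabolites"))

#' @rdname MetabolicModel-class
#' @export
setGeneric("reactions", function(x) standardGeneric("reactions"))

#' @rdname MetabolicModel-class
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))

#' @rdname MetabolicModel-class
#' @export
setGeneric("stoichiometricMatrix", function(x) standardGeneric("stoichiometricMatrix"))

#' @rdname FluxSolution-class
#' @export
setGeneric("fluxes", function(x) standardGeneric("fluxes"))

#' @rdname FluxSolution-class
#' @export
setGeneric("objectiveValue", function(x) standardGeneric("objectiveValue"))

#' @rdname FluxSolution-class
#' @export
setGeneric("solutionStatus", function(x) standardGeneric("solutionStatus"))
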