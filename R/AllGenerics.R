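#' @import methods
NULL

#' Accessors for hypergraph containers
#'
#' `hyperarcs()` returns the hyperarc table (one row per single-target
#' hyperarc, with a list-column of source vertex ids); `vertices()` returns the
#' vertex table with compound and organism annotation.
#'
#' @param x a [Hypergraph-class] or [ConsortiumInstance-class].
#' @return A `data.frame`.
#' @aliases hyperarcs vertices
#' @export
setGeneric("hyperarcs", function(x) standardGeneric("hyperarcs"))

#' @rdname hyperarcs
#' @export
setGeneric("vertices", function(x) standardGeneric("vertices"))

#' @rdname spreadness
#' @export
setGeneric("spreadness", function(x, arcIds = NULL) standardGeneric("spreadness"))

#' @rdname spreadness
#' @export
setGeneric("totalSpreadness", function(x) standardGeneric("totalSpreadness"))

#' @rdname closure
#' @export
setGeneric("closure", function(x, arcIds, start) standardGeneric("closure"))

#' @rdname isRooted
#' @export
setGeneric("isRooted", function(x, arcIds, sources) standardGeneric("isRooted"))

#' @rdname solutionWeight
#' @export
setGeneric("solutionWeight", function(x, arcIds, perReaction = FALSE)
  standardGeneric("solutionWeight"))

#' @rdname arcGraph
#' @export
setGeneric("arcGraph", function(x) standardGeneric("arcGraph"))

#' @rdname ConsortiumInstance-class
#' @export
setGeneric("sources", function(x) standardGeneric("sources"))

#' @rdname ConsortiumInstance-class
#' @export
setGeneric("targets", function(x) standardGeneric("targets"))

#' @rdname ConsortiumInstance-class
#' @export
setGeneric("workerOrganisms", function(x) standardGeneric("workerOrganisms"))

#' @rdname ConsortiumInstance-class
#' @export
setGeneric("weightConfig", function(x) standardGeneric("weightConfig"))

#' @rdname SolutionHypertree-class
#' @export
setGeneric("solutionArcs", function(x) standardGeneric("solutionArcs"))

#' @rdname SolutionHypertree-class
#' @export
setGeneric("arcOrdering", function(x) standardGeneric("arcOrdering"))

#' @rdname SolutionHypertree-class
#' @export
setGeneric("totalWeight", function(x) standardGeneric("totalWeight"))

#' @rdname SolutionHypertree-class
#' @export
setGeneric("breakdown", function(x) standardGeneric("breakdown"))

#' @rdname DshOutcome-class
#' @export
setGeneric("solverStatus", function(x) standardGeneric("solverStatus"))

#' @rdname DshOutcome-class
#' @export
setGeneric("optimalWeight", function(x) standardGeneric("optimalWeight"))

#' @rdname DshOutcome-class
#' @export
setGeneric("solutions", function(x) standardGeneric("solutions"))

#' @rdname solveDsh
#' @export
setGeneric("solveDsh", function(x, ...) standardGeneric("solveDsh"))

#' @rdname enumerateOptimal
#' @export
setGeneric("enumerateOptimal", function(x, ...) standardGeneric("enumerateOptimal"))

#' @rdname bruteForceDsh
#' @export
setGeneric("bruteForceDsh", function(x, ...) standardGeneric("bruteForceDsh"))

#' @rdname compressInstance
#' @export
setGeneric("compressInstance", function(x, ...) standardGeneric("compressInstance"))
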