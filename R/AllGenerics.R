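#' Accessors for PIM and logical-model objects
#'
#' Slot access is considered internal; these generics are the supported way
#' to read the pieces of a \linkS4class{PIM}, \linkS4class{InteractionGraph}
#' or \linkS4class{LogicalModel}.
#'
#' @param x a \linkS4class{PIM}, \linkS4class{InteractionGraph} or
#'   \linkS4class{LogicalModel}.
#' @param node integer process id (for \code{parameterTable}).
#' @return \code{molecules}: named list of site-name vectors;
#'   \code{processNodes}, \code{influences}, \code{lNodes}: data.frames;
#'   \code{parameterTable}: a \linkS4class{ParameterTable};
#'   \code{thresholds}: list(t1, t2, overrides);
#'   \code{gateFunctions}: named list of gates.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("molecules", function(x) standardGeneric("molecules"))

#' @rdname accessors
#' @export
setGeneric("processNodes", function(x) standardGeneric("processNodes"))

#' @rdname accessors
#' @export
setGeneric("influences", function(x) standardGeneric("influences"))

#' @rdname accessors
#' @export
setGeneric("parameterTable", function(x, node) standardGeneric("parameterTable"))

#' @rdname accessors
#' @export
setGeneric("thresholds", function(x) standardGeneric("thresholds"))

#' @rdname accessors
#' @export
setGeneric("lNodes", function(x) standardGeneric("lNodes"))

#' @rdname accessors
#' @export
setGeneric("lEdges", function(x) standardGeneric("lEdges"))

#' @rdname accessors
#' @export
setGeneric("gateFunctions", function(x) standardGeneric("gateFunctions"))

#' @rdname accessors
#' @export
setMethod("molecules", "PIM", function(x) x@molecules)

#' @rdname accessors
#' @export
setMethod("processNodes", "PIM", function(x) x@processes)

#' @rdname accessors
#' @export
setMethod("influences", "PIM", function(x) x@influences)

#' @rdname accessors
#' @export
setMethod("parameterTable", "PIM", function(x, node) {
  key <- as.character(node)
  if (!key %in% names(x@tables))
    stop("no parameter table for node ", node)
  x@tables[[key]]
})

#' @rdname accessors
#' @export
setMethod("thresholds", "PIM", function(x) x@thresholds)

#' @rdname accessors
#' @export
setMethod("lNodes", "InteractionGraph", function(x) x@nodes)

#' @rdname accessors
#' @export
setMethod("lNodes", "LogicalModel", function(x) x@graph@nodes)

#' @rdname accessors
#' @export
setMethod("lEdges", "InteractionGraph", function(x) x@edges)

#' @rdname accessors
#' @export
setMethod("lEdges", "LogicalModel", function(x) x@graph@edges)

#' @rdname accessors
#' @export
setMethod("gateFunctions", "LogicalModel", function(x) x@gates)
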