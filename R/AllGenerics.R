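#' @rdname knowledgegraph-accessors
#' @export
setGeneric("numEntities", function(x) standardGeneric("numEntities"))

#' @rdname knowledgegraph-accessors
#' @export
setGeneric("numRelations",
           function(x, augmented = FALSE) standardGeneric("numRelations"))

#' @rdname knowledgegraph-accessors
#' @export
setGeneric("entityNames", function(x) standardGeneric("entityNames"))

#' @rdname knowledgegraph-accessors
#' @export
setGeneric("relationNames",
           function(x, augmented = FALSE) standardGeneric("relationNames"))

#' @rdname knowledgegraph-accessors
#' @export
setGeneric("tripleSplit", function(x, split) standardGeneric("tripleSplit"))

#' @rdname model-accessors
#' @export
setGeneric("embedDim", function(x) standardGeneric("embedDim"))

#' @rdname model-accessors
#' @export
setGeneric("cpFactors", function(x) standardGeneric("cpFactors"))

#' @rdname model-accessors
#' @export
setGeneric("trainingLog", function(x) standardGeneric("trainingLog"))

#' @rdname model-accessors
#' @export
setGeneric("modelConfig", function(x) standardGeneric("modelConfig"))

#' @rdname rankingresult-accessors
#' @export
setGeneric("queryRanks", function(x) standardGeneric("queryRanks"))
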