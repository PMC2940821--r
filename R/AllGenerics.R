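#' @rdname varianceOf
#' @export
setGeneric("varianceOf", function(model, x) standardGeneric("varianceOf"))

#' @rdname accessors
#' @export
setGeneric("stimulusIds", function(object) standardGeneric("stimulusIds"))

#' @rdname accessors
#' @export
setGeneric("inhibitorIds", function(object) standardGeneric("inhibitorIds"))

#' @rdname accessors
#' @export
setGeneric("inhibitorTargets", function(object) standardGeneric("inhibitorTargets"))

#' @rdname accessors
#' @export
setGeneric("timePoints", function(object) standardGeneric("timePoints"))

#' @rdname accessors
#' @export
setGeneric("proteins", function(object) standardGeneric("proteins"))

#' @rdname accessors
#' @export
setGeneric("edgeCount", function(object) standardGeneric("edgeCount"))

#' @rdname accessors
#' @export
setGeneric("edges", function(object) standardGeneric("edges"))

#' @rdname accessors
#' @export
setGeneric("networkNodes", function(object) standardGeneric("networkNodes"))

#' @rdname accessors
#' @export
setGeneric("rankedLinks", function(object) standardGeneric("rankedLinks"))

#' @rdname accessors
#' @export
setGeneric("booleanTables", function(object) standardGeneric("booleanTables"))

#' @rdname accessors
#' @export
setGeneric("network", function(object) standardGeneric("network"))
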