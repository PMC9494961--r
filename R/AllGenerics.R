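#' @rdname MitoGenome-accessors
#' @export
setGeneric("genomeID", function(x) standardGeneric("genomeID"))

#' @rdname MitoGenome-accessors
#' @export
setGeneric("genomeSeq", function(x) standardGeneric("genomeSeq"))

#' @rdname MitoGenome-accessors
#' @export
setGeneric("genomeLength", function(x) standardGeneric("genomeLength"))

#' @rdname MitoGenome-accessors
#' @export
setGeneric("featureTable", function(x) standardGeneric("featureTable"))

#' @rdname GeneOrder-accessors
#' @export
setGeneric("orderLabels", function(x) standardGeneric("orderLabels"))

#' @rdname GeneOrder-accessors
#' @export
setGeneric("orderStrands", function(x) standardGeneric("orderStrands"))

#' @rdname GeneOrder-accessors
#' @export
setGeneric("orderAnchor", function(x) standardGeneric("orderAnchor"))
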