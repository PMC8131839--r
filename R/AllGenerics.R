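#' @rdname segSeqs
#' @export
setGeneric("segSeqs", function(x) standardGeneric("segSeqs"))

#' @rdname segSeqs
#' @export
setGeneric("segLinks", function(x) standardGeneric("segLinks"))

#' @rdname segSeqs
#' @export
setGeneric("segMembers", function(x) standardGeneric("segMembers"))

#' @rdname segSeqs
#' @export
setGeneric("nSegs", function(x) standardGeneric("nSegs"))

#' @rdname segSeqs
#' @export
setGeneric("graphType", function(x) standardGeneric("graphType"))

#' @rdname condense
#' @export
setGeneric("condense", function(x, ...) standardGeneric("condense"))

#' @rdname terminalEdges
#' @export
setGeneric("terminalEdges", function(x, ...) standardGeneric("terminalEdges"))

#' @rdname gaThreshold
#' @export
setGeneric("gaThreshold", function(x) standardGeneric("gaThreshold"))

#' @rdname gaThreshold
#' @export
setGeneric("gaThreshold<-", function(x, value) standardGeneric("gaThreshold<-"))
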