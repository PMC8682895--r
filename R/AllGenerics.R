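#' @rdname KinomeSignal-accessors
#' @export
setGeneric("signalRecords", function(x) standardGeneric("signalRecords"))

#' @rdname KinomeSignal-accessors
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' @rdname KinomeSignal-accessors
#' @export
setGeneric("peptideInfo", function(x) standardGeneric("peptideInfo"))

#' @rdname KinomeSignal-accessors
#' @export
setGeneric("quantType", function(x) standardGeneric("quantType"))

#' @rdname KinomeSignal-accessors
#' @export
setGeneric("sourceMeta", function(x) standardGeneric("sourceMeta"))

#' @rdname KinomeSignal-accessors
#' @export
setGeneric("qcReport", function(x) standardGeneric("qcReport"))

#' @rdname KinomeModel-accessors
#' @export
setGeneric("modelFits", function(x) standardGeneric("modelFits"))

#' @rdname KinomeModel-accessors
#' @export
setGeneric("normalizedFits", function(x) standardGeneric("normalizedFits"))

#' @rdname KinomeModel-accessors
#' @export
setGeneric("groupedSignals", function(x) standardGeneric("groupedSignals"))

#' @rdname KinomeDiff-accessors
#' @export
setGeneric("diffTable", function(x) standardGeneric("diffTable"))

#' @rdname KinaseScores-accessors
#' @export
setGeneric("scoreTable", function(x) standardGeneric("scoreTable"))

#' @rdname KinaseScores-accessors
#' @export
setGeneric("averagedScores", function(x) standardGeneric("averagedScores"))

#' @rdname KinaseMapping-accessors
#' @export
setGeneric("peptidePool", function(x) standardGeneric("peptidePool"))

#' @rdname KinaseMapping-accessors
#' @export
setGeneric("kinaseNames", function(x) standardGeneric("kinaseNames"))

#' @rdname KinaseNetwork-accessors
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname KinaseNetwork-accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))
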