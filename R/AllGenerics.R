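#' @rdname ChannelStack-class
#' @param object,x a \linkS4class{ChannelStack}
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname ChannelStack-class
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname ChannelStack-class
#' @param marker marker name
#' @export
setGeneric("getChannel", function(x, marker) standardGeneric("getChannel"))

#' @rdname MarkerPanel-class
#' @export
setGeneric("markerNames", function(x) standardGeneric("markerNames"))

#' @rdname MarkerPanel-class
#' @export
setGeneric("cellTypes", function(x) standardGeneric("cellTypes"))

#' @rdname MarkerPanel-class
#' @export
setGeneric("tumorType", function(x) standardGeneric("tumorType"))

#' @rdname MarkerPanel-class
#' @export
setGeneric("immuneTypes", function(x) standardGeneric("immuneTypes"))

#' @rdname LesionSet-class
#' @export
setGeneric("lesionTable", function(x) standardGeneric("lesionTable"))

#' @rdname LesionSet-class
#' @export
setGeneric("immuneMembers", function(x) standardGeneric("immuneMembers"))

#' @rdname SimTruth-class
#' @export
setGeneric("trueLesions", function(x) standardGeneric("trueLesions"))

#' @rdname SimTruth-class
#' @export
setGeneric("trueTypes", function(x) standardGeneric("trueTypes"))
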