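#' @include utils.R
NULL

#' Event measurement matrix
#'
#' @param object a \linkS4class{EventMatrix} (or other marrowSOM object).
#' @name accessors
NULL

#' @describeIn accessors events-by-channels measurement matrix.
#' @export
setGeneric("exprs", function(object) standardGeneric("exprs"))

#' @describeIn accessors ordered channel identifiers.
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))

#' @describeIn accessors per-channel stain/marker labels (may be empty strings).
#' @export
setGeneric("markerNames", function(object) standardGeneric("markerNames"))

#' @describeIn accessors per-event sample-origin labels.
#' @export
setGeneric("sampleIds", function(object) standardGeneric("sampleIds"))

#' @describeIn accessors processing state: one of \code{"raw"},
#'   \code{"compensated"}, \code{"transformed"}, \code{"scaled"}.
#' @export
setGeneric("eventState", function(object) standardGeneric("eventState"))

#' @describeIn accessors simulator ground-truth population per event
#'   (zero-length when unknown).
#' @export
setGeneric("truthLabels", function(object) standardGeneric("truthLabels"))

#' @describeIn accessors number of events (rows).
#' @export
setGeneric("nEvents", function(object) standardGeneric("nEvents"))

#' @describeIn accessors number of channels (columns).
#' @export
setGeneric("nChannels", function(object) standardGeneric("nChannels"))

#' @describeIn accessors number of SOM nodes.
#' @export
setGeneric("nNodes", function(object) standardGeneric("nNodes"))

#' @describeIn accessors node codebook matrix (nodes x channels, scaled space).
#' @export
setGeneric("codebook", function(object) standardGeneric("codebook"))

#' @describeIn accessors per-sample node-occupancy matrix of a template.
#' @export
setGeneric("occupancy", function(object) standardGeneric("occupancy"))

#' @describeIn accessors node-level statistics table of a template.
#' @export
setGeneric("nodeStats", function(object) standardGeneric("nodeStats"))

#' @describeIn accessors node labels of a template.
#' @export
setGeneric("nodeLabels", function(object) standardGeneric("nodeLabels"))

#' @describeIn accessors replace node labels of a template.
#' @param value replacement value.
#' @export
setGeneric("nodeLabels<-", function(object, value) standardGeneric("nodeLabels<-"))
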