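#' @include AllGenerics.R
NULL

.EVENT_STATES <- c("raw", "compensated", "transformed", "scaled")
.CHANNEL_ROLES <- c("fluorescence", "side_scatter", "forward_scatter", "time")

#' EventMatrix: list-mode cytometry events
#'
#' Events-by-channels measurement table with per-event sample origin and a
#' processing-state flag. Column names of \code{exprs} are the channel
#' identifiers; \code{markerNames} carries the stain labels (possibly empty
#' per channel). A simulator ground-truth population label per event may be
#' attached in \code{truth}; it is carried through preprocessing and written
#' to CSV exports, never to a measurement channel.
#'
#' @slot exprs numeric matrix, events x channels, all values finite.
#' @slot markerNames character, one per channel.
#' @slot sampleIds character, one per event.
#' @slot state one of \code{"raw"}, \code{"compensated"}, \code{"transformed"},
#'   \code{"scaled"}.
#' @slot truth character, one per event, or length zero.
#' @export
setClass("EventMatrix",
  representation(exprs = "matrix", markerNames = "character",
                 sampleIds = "character", state = "character",
                 truth = "character"),
  prototype(truth = character(0)))

setValidity("EventMatrix", function(object) {
  v <- object@exprs
  msgs <- character(0)
  if (!is.numeric(v)) msgs <- c(msgs, "exprs must be numeric")
  if (is.null(colnames(v))) msgs <- c(msgs, "exprs must have channel names as colnames")
  if (length(object@markerNames) != ncol(v))
    msgs <- c(msgs, "markerNames length must equal channel count")
  if (length(object@sampleIds) != nrow(v))
    msgs <- c(msgs, "sampleIds length must equal event count")
  if (length(object@truth) != 0 && length(object@truth) != nrow(v))
    msgs <- c(msgs, "truth must be empty or one per event")
  if (!(object@state %in% .EVENT_STATES))
    msgs <- c(msgs, sprintf("state must be one of %s", paste(.EVENT_STATES, collapse = ", ")))
  if (length(v) && any(!is.finite(v)))
    msgs <- c(msgs, "all values must be finite")
  if (length(msgs)) msgs else TRUE
})

#' Construct an EventMatrix
#'
#' @param values numeric matrix (events x channels) with channel names as
#'   column names, or column names supplied via \code{channelNames}.
#' @param channelNames optional channel identifiers overriding column names.
#' @param markerNames optional marker labels (default: empty per channel).
#' @param sampleIds per-event sample labels, recycled if length one.
#' @param state processing state flag.
#' @param truth optional per-event ground-truth population label.
#' @return an \linkS4class{EventMatrix}.
#' @export
eventMatrix <- function(values, channelNames = NULL, markerNames = NULL,
                        sampleIds = "sample1", state = "raw",
                        truth = character(0)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.null(channelNames)) colnames(values) <- channelNames
  if (is.null(colnames(values)))
    colnames(values) <- paste0("ch", seq_len(ncol(values)))
  if (is.null(markerNames)) markerNames <- rep("", ncol(values))
  if (length(sampleIds) == 1L) sampleIds <- rep(sampleIds, nrow(values))
  new("EventMatrix", exprs = values, markerNames = as.character(markerNames),
      sampleIds = as.character(sampleIds), state = state,
      truth = as.character(truth))
}

#' @rdname accessors
#' @export
setMethod("exprs", "EventMatrix", function(object) object@exprs)
#' @rdname accessors
#' @export
setMethod("channelNames", "EventMatrix", function(object) colnames(object@exprs))
#' @rdname accessors
#' @export
setMethod("markerNames", "EventMatrix", function(object) object@markerNames)
#' @rdname accessors
#' @export
setMethod("sampleIds", "EventMatrix", function(object) object@sampleIds)
#' @rdname accessors
#' @export
setMethod("eventState", "EventMatrix", function(object) object@state)
#' @rdname accessors
#' @export
setMethod("truthLabels", "EventMatrix", function(object) object@truth)
#' @rdname accessors
#' @export
setMethod("nEvents", "EventMatrix", function(object) nrow(object@exprs))
#' @rdname accessors
#' @export
setMethod("nChannels", "EventMatrix", function(object) ncol(object@exprs))

setMethod("show", "EventMatrix", function(object) {
  cat(sprintf("EventMatrix: %d events x %d channels [%s]\n",
              nrow(object@exprs), ncol(object@exprs), object@state))
  cat("  channels:", paste(colnames(object@exprs), collapse = ", "), "\n")
  mk <- object@markerNames[nzchar(object@markerNames)]
  if (length(mk)) cat("  markers: ", paste(mk, collapse = ", "), "\n")
  cat(sprintf("  samples: %d unique\n", length(unique(object@sampleIds))))
})

#' Subset events (rows) of an EventMatrix
#'
#' @param x an \linkS4class{EventMatrix}.
#' @param i row (event) index.
#' @param j unused.
#' @param drop ignored.
#' @param ... ignored.
#' @export
setMethod("[", "EventMatrix", function(x, i, j, ..., drop = FALSE) {
  new("EventMatrix", exprs = x@exprs[i, , drop = FALSE],
      markerNames = x@markerNames, sampleIds = x@sampleIds[i],
      state = x@state,
      truth = if (length(x@truth)) x@truth[i] else character(0))
})

#' PanelDefinition: one antibody combination
#'
#' Channel roles, marker names, spillover matrix and per-channel transform
#' parameters for a staining panel. The spillover matrix (when present) is
#' square over the fluorescence channels with unit diagonal, rows = source
#' stain, columns = detector.
#'
#' @slot name panel name, e.g. \code{"AML-B"}.
#' @slot channels data.frame with columns \code{channel}, \code{marker},
#'   \code{role} (fluorescence / side_scatter / forward_scatter / time),
#'   \code{transform} (\code{"arcsinh"} or \code{"identity"}) and
#'   \code{cofactor} (positive).
#' @slot spillover numeric matrix (0 x 0 when absent).
#' @export
setClass("PanelDefinition",
  representation(name = "character", channels = "data.frame",
                 spillover = "matrix"))

setValidity("PanelDefinition", function(object) {
  ch <- object@channels
  msgs <- character(0)
  need <- c("channel", "marker", "role", "transform", "cofactor")
  if (!all(need %in% names(ch)))
    return(sprintf("channels must have columns %s", paste(need, collapse = ", ")))
  if (!all(ch$role %in% .CHANNEL_ROLES))
    msgs <- c(msgs, "unknown channel role")
  if (!all(ch$transform %in% c("arcsinh", "identity")))
    msgs <- c(msgs, "transform must be arcsinh or identity")
  if (any(ch$cofactor <= 0))
    msgs <- c(msgs, "cofactors must be positive")
  if (anyDuplicated(ch$channel))
    msgs <- c(msgs, "duplicate channel names")
  nf <- sum(ch$role == "fluorescence")
  sp <- object@spillover
  if (length(sp)) {
    if (nrow(sp) != ncol(sp)) msgs <- c(msgs, "spillover must be square")
    else {
      if (nrow(sp) != nf)
        msgs <- c(msgs, "spillover dimension must match fluorescence channel count")
      if (any(abs(diag(sp) - 1) > 1e-12))
        msgs <- c(msgs, "spillover must have unit diagonal")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a PanelDefinition
#'
#' @param name panel name.
#' @param channels data.frame with columns \code{channel}, \code{marker},
#'   \code{role}; optional \code{transform}, \code{cofactor} (defaults:
#'   arcsinh/150 for fluorescence, arcsinh/10000 for side scatter, identity
#'   for forward scatter and time).
#' @param spillover optional square spillover matrix over the fluorescence
#'   channels (rows = source, columns = detector, unit diagonal).
#' @return a \linkS4class{PanelDefinition}.
#' @export
panelDefinition <- function(name, channels, spillover = NULL) {
  channels <- as.data.frame(channels, stringsAsFactors = FALSE)
  if (is.null(channels$marker)) channels$marker <- ""
  if (is.null(channels$transform))
    channels$transform <- ifelse(channels$role %in% c("fluorescence", "side_scatter"),
                                 "arcsinh", "identity")
  if (is.null(channels$cofactor))
    channels$cofactor <- ifelse(channels$role == "side_scatter", 10000,
                         ifelse(channels$role == "fluorescence", 150, 1))
  if (is.null(spillover)) spillover <- matrix(numeric(0), 0, 0)
  new("PanelDefinition", name = name, channels = channels,
      spillover = as.matrix(spillover))
}

setMethod("show", "PanelDefinition", function(object) {
  ch <- object@channels
  cat(sprintf("PanelDefinition '%s': %d channels (%d fluorescence)\n",
              object@name, nrow(ch), sum(ch$role == "fluorescence")))
  lab <- ifelse(nzchar(ch$marker), paste0(ch$channel, "/", ch$marker), ch$channel)
  cat(" ", paste(lab, collapse = ", "), "\n")
  if (length(object@spillover)) cat("  spillover: present\n")
})

#' Clustering channels of a panel
#'
#' Channels entering the SOM space: all fluorescence channels plus side
#' scatter; forward scatter optionally.
#'
#' @param panel a \linkS4class{PanelDefinition}.
#' @param includeForwardScatter include forward scatter as well.
#' @return character vector of channel names in panel order.
#' @export
clusteringChannels <- function(panel, includeForwardScatter = FALSE) {
  roles <- c("fluorescence", "side_scatter",
             if (includeForwardScatter) "forward_scatter")
  ch <- panel@channels
  ch$channel[ch$role %in% roles]
}

#' ScalingStats: frozen per-channel standardization parameters
#'
#' Location/spread used to scale transformed events into SOM space. Frozen
#' into a reference template so patient samples are mapped in the reference's
#' coordinate system.
#'
#' @slot channels channel order the stats apply to.
#' @slot location per-channel location (median of the training data).
#' @slot spread per-channel spread (SD, floored).
#' @export
setClass("ScalingStats",
  representation(channels = "character", location = "numeric",
                 spread = "numeric"))

setValidity("ScalingStats", function(object) {
  if (length(object@location) != length(object@channels) ||
      length(object@spread) != length(object@channels))
    return("location/spread length must match channels")
  if (length(object@spread) && any(object@spread <= 0))
    return("spread must be positive")
  TRUE
})

#' SOMModel: trained self-organizing map
#'
#' Rectangular-grid batch SOM codebook in scaled space, with the frozen
#' scaling statistics and training metadata needed to map any new sample
#' reproducibly. Node ids are 1-based in row-major grid order.
#'
#' @slot gridRows,gridCols grid dimensions (default reference grid 10 x 10,
#'   i.e. 100 nodes).
#' @slot codebook nodes x channels matrix in scaled space.
#' @slot scaling the \linkS4class{ScalingStats} used for training.
#' @slot meta list: epochs, radiusInitial, radiusFinal, schedule, seed.
#' @export
setClass("SOMModel",
  representation(gridRows = "integer", gridCols = "integer",
                 codebook = "matrix", scaling = "ScalingStats",
                 meta = "list"))

setValidity("SOMModel", function(object) {
  msgs <- character(0)
  if (object@gridRows < 1L || object@gridCols < 1L)
    msgs <- c(msgs, "grid dimensions must be positive")
  if (nrow(object@codebook) != object@gridRows * object@gridCols)
    msgs <- c(msgs, "codebook row count must equal gridRows * gridCols")
  if (length(object@codebook) && any(!is.finite(object@codebook)))
    msgs <- c(msgs, "codebook must be finite")
  if (is.null(object@meta$seed))
    msgs <- c(msgs, "training seed must be recorded")
  if (length(msgs)) msgs else TRUE
})

#' @rdname accessors
#' @export
setMethod("nNodes", "SOMModel", function(object) nrow(object@codebook))
#' @rdname accessors
#' @export
setMethod("codebook", "SOMModel", function(object) object@codebook)

setMethod("show", "SOMModel", function(object) {
  cat(sprintf("SOMModel: %d x %d grid (%d nodes), %d channels\n",
              object@gridRows, object@gridCols, nrow(object@codebook),
              ncol(object@codebook)))
  cat(sprintf("  trained: %d epochs, radius %.2f -> %.2f, seed %s\n",
              object@meta$epochs %||% NA_integer_,
              object@meta$radiusInitial %||% NA_real_,
              object@meta$radiusFinal %||% NA_real_,
              format(object@meta$seed)))
})

#' MSTGraph: minimal spanning tree over SOM nodes
#'
#' Minimum spanning tree of the complete graph over codebook vectors with
#' Euclidean edge weights in scaled space, plus a 2-D display layout.
#'
#' @slot nNodes node count.
#' @slot edges data.frame \code{from}, \code{to}, \code{weight}
#'   (\code{from < to}, sorted).
#' @slot layout nodes x 2 coordinate matrix (0 x 2 until laid out).
#' @export
setClass("MSTGraph",
  representation(nNodes = "integer", edges = "data.frame", layout = "matrix"))

setValidity("MSTGraph", function(object) {
  msgs <- character(0)
  if (object@nNodes >= 1L && nrow(object@edges) != object@nNodes - 1L)
    msgs <- c(msgs, "edge count must be node count - 1")
  if (nrow(object@layout) && nrow(object@layout) != object@nNodes)
    msgs <- c(msgs, "layout must have one row per node")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "MSTGraph", function(object) {
  cat(sprintf("MSTGraph: %d nodes, %d edges, total weight %.4f%s\n",
              object@nNodes, nrow(object@edges), sum(object@edges$weight),
              if (nrow(object@layout)) ", layout present" else ""))
})

#' ReferenceTemplate: frozen per-panel reference
#'
#' The frozen product of a merged-normal reference build: panel, trained SOM,
#' MST, node-level statistics over the merged cohort, per-normal-sample
#' occupancy rows, per-marker phenotype bin edges, node labels, and
#' provenance (sample ids, seed, package version). Patient samples are mapped
#' onto this object without ever modifying it.
#'
#' @slot panel the \linkS4class{PanelDefinition}.
#' @slot model the frozen \linkS4class{SOMModel}.
#' @slot tree the \linkS4class{MSTGraph} with layout.
#' @slot nodeStats per-node statistics data.frame over the merged cohort.
#' @slot occupancy normal-samples x nodes matrix of occupancy fractions
#'   (each row sums to 1).
#' @slot markerBreaks markers x 3 matrix of 20/50/80th percentiles of the
#'   merged transformed intensity distribution per clustering channel.
#' @slot nodeLabels list of character vectors, one per node.
#' @slot provenance list: sampleIds, seed, nEvents, version, panel name.
#' @export
setClass("ReferenceTemplate",
  representation(panel = "PanelDefinition", model = "SOMModel",
                 tree = "MSTGraph", nodeStats = "data.frame",
                 occupancy = "matrix", markerBreaks = "matrix",
                 nodeLabels = "list", provenance = "list"))

setValidity("ReferenceTemplate", function(object) {
  msgs <- character(0)
  n <- nrow(object@model@codebook)
  if (ncol(object@occupancy) != n)
    msgs <- c(msgs, "occupancy column count must equal node count")
  if (nrow(object@occupancy)) {
    rs <- rowSums(object@occupancy)
    if (any(abs(rs - 1) > 1e-9))
      msgs <- c(msgs, "each occupancy row must sum to 1 within 1e-9")
  }
  if (length(object@nodeLabels) && length(object@nodeLabels) != n)
    msgs <- c(msgs, "nodeLabels must have one entry per node")
  if (length(msgs)) msgs else TRUE
})

#' @rdname accessors
#' @export
setMethod("nNodes", "ReferenceTemplate", function(object) nNodes(object@model))
#' @rdname accessors
#' @export
setMethod("codebook", "ReferenceTemplate", function(object) codebook(object@model))
#' @rdname accessors
#' @export
setMethod("occupancy", "ReferenceTemplate", function(object) object@occupancy)
#' @rdname accessors
#' @export
setMethod("nodeStats", "ReferenceTemplate", function(object) object@nodeStats)
#' @rdname accessors
#' @export
setMethod("nodeLabels", "ReferenceTemplate", function(object) object@nodeLabels)
#' @rdname accessors
#' @export
setMethod("nodeLabels<-", "ReferenceTemplate", function(object, value) {
  object@nodeLabels <- value
  methods::validObject(object)
  object
})

setMethod("show", "ReferenceTemplate", function(object) {
  cat(sprintf("ReferenceTemplate [%s]: %d nodes, %d normal samples, %d events\n",
              object@panel@name, nNodes(object), nrow(object@occupancy),
              object@provenance$nEvents %||% NA_integer_))
  nl <- sum(lengths(object@nodeLabels) > 0)
  cat(sprintf("  labeled nodes: %d; seed %s; version %s\n", nl,
              format(object@provenance$seed),
              object@provenance$version %||% "?"))
})

#' NormalRanges: per-node normal occupancy ranges
#'
#' Mean, floored SD, min and max node occupancy across the normal cohort;
#' the basis for z-scoring patient samples. The SD floor keeps z-scores
#' defined (and large but finite) for nodes empty in all normals - the
#' MRD-relevant case.
#'
#' @slot mean,sd,min,max per-node statistics across normal samples.
#' @slot sdFloor the floor applied to \code{sd}.
#' @export
setClass("NormalRanges",
  representation(mean = "numeric", sd = "numeric", min = "numeric",
                 max = "numeric", sdFloor = "numeric"))

setValidity("NormalRanges", function(object) {
  n <- length(object@mean)
  if (length(object@sd) != n || length(object@min) != n || length(object@max) != n)
    return("mean/sd/min/max must have equal length")
  if (any(object@min > object@mean + 1e-12) || any(object@mean > object@max + 1e-12))
    return("min <= mean <= max must hold per node")
  if (any(object@sd < object@sdFloor - 1e-15))
    return("sd must be >= sdFloor")
  TRUE
})

setMethod("show", "NormalRanges", function(object) {
  cat(sprintf("NormalRanges over %d nodes (sd floor %.3g)\n",
              length(object@mean), object@sdFloor))
})

#' MappedSample: a sample mapped onto a frozen reference
#'
#' @slot sampleId sample label.
#' @slot assignments per-event node id (1-based).
#' @slot occupancy per-node occupancy fraction (sums to 1).
#' @slot eventCount number of events mapped.
#' @export
setClass("MappedSample",
  representation(sampleId = "character", assignments = "integer",
                 occupancy = "numeric", eventCount = "integer"))

setValidity("MappedSample", function(object) {
  msgs <- character(0)
  if (length(object@assignments) != object@eventCount)
    msgs <- c(msgs, "assignments must cover all events")
  if (object@eventCount > 0L && abs(sum(object@occupancy) - 1) > 1e-9)
    msgs <- c(msgs, "occupancy must sum to 1 within 1e-9")
  if (length(msgs)) msgs else TRUE
})

#' @rdname accessors
#' @export
setMethod("occupancy", "MappedSample", function(object) object@occupancy)

setMethod("show", "MappedSample", function(object) {
  cat(sprintf("MappedSample '%s': %d events over %d nodes\n",
              object@sampleId, object@eventCount, length(object@occupancy)))
})

#' ComparisonReport: patient sample vs normal ranges
#'
#' Per-node occupancy, normal mean, z-score, log2 fold-change (with
#' pseudocount) and excess/deficit flag, plus an aggregate summary: total
#' excess burden (percent of analyzed events in excess-flagged nodes) and
#' the labels attached to deficit-flagged nodes.
#'
#' @slot nodeTable per-node data.frame.
#' @slot summary list: excessBurden, excessNodes, deficitNodes, deficitLabels.
#' @slot thresholds list of thresholds used.
#' @export
setClass("ComparisonReport",
  representation(nodeTable = "data.frame", summary = "list",
                 thresholds = "list"))

setMethod("show", "ComparisonReport", function(object) {
  s <- object@summary
  cat(sprintf("ComparisonReport: excess burden %.2f%% (%d nodes), %d deficit nodes\n",
              s$excessBurden, length(s$excessNodes), length(s$deficitNodes)))
  if (length(s$deficitLabels))
    cat("  deficit labels:", paste(s$deficitLabels, collapse = ", "), "\n")
})

#' PhenotypeRuleSet: marker rules naming populations
#'
#' Declarative rules assigning population labels to nodes from their
#' per-marker levels (neg / lo / pos / hi). A \code{pos} clause matches
#' levels pos or hi; \code{hi}, \code{lo} and \code{neg} match exactly.
#' Optional per-marker absolute bin edges override the default quantile
#' binning (useful for markers, such as CD34, whose merged distribution is
#' dominated by the negative mode).
#'
#' @slot rules list of lists: \code{label}, \code{priority}, \code{clauses}
#'   (named character: marker -> level).
#' @slot breaks named list: marker -> numeric(3) absolute bin edges.
#' @export
setClass("PhenotypeRuleSet",
  representation(rules = "list", breaks = "list"))

setValidity("PhenotypeRuleSet", function(object) {
  for (r in object@rules) {
    if (is.null(r$label) || !nzchar(r$label)) return("each rule needs a label")
    if (length(r$clauses) < 1L) return("each rule needs at least one clause")
    if (!all(r$clauses %in% c("neg", "lo", "pos", "hi")))
      return("clause levels must be neg/lo/pos/hi")
  }
  TRUE
})

setMethod("show", "PhenotypeRuleSet", function(object) {
  cat(sprintf("PhenotypeRuleSet: %d rules\n", length(object@rules)))
  for (r in object@rules)
    cat(sprintf("  %s: %s\n", r$label,
                paste(names(r$clauses), r$clauses, sep = "=", collapse = " ")))
})
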