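#' @include AllClasses.R
NULL

#' Map a patient sample onto a frozen reference
#'
#' Compensates, transforms and scales the sample with the template's frozen
#' scaling statistics, then assigns every event to its best-matching node of
#' the frozen codebook. The template is never modified by mapping.
#'
#' @param template a \linkS4class{ReferenceTemplate}.
#' @param events a raw \linkS4class{EventMatrix} compatible with the
#'   template's panel (missing channels raise a channel-mismatch error).
#' @return a \linkS4class{MappedSample}.
#' @export
mapSample <- function(template, events) {
  panel <- template@panel
  merged <- mergeEvents(list(events), panel)  # channel match + panel order
  scaling <- template@model@scaling
  incFSC <- any(panel@channels$channel[panel@channels$role == "forward_scatter"]
                %in% scaling@channels)
  ss <- .preprocessEvents(merged, panel, stats = scaling,
                          includeForwardScatter = incFSC)
  assignments <- assignBMU(ss$events, template@model)
  n <- nNodes(template)
  occ <- tabulate(assignments, nbins = n) / max(1L, length(assignments))
  new("MappedSample", sampleId = .sampleLabel(events, 1L),
      assignments = assignments, occupancy = occ,
      eventCount = length(assignments))
}

#' Comparison thresholds
#'
#' Defaults: a node is flagged \emph{excess} when its z-score exceeds
#' \code{zHi = 3.5} and its occupancy exceeds \code{minExcess = 0.0005};
#' \emph{deficit} when its normal mean occupancy exceeds
#' \code{minDeficitBase = 0.005} and its occupancy falls below
#' \code{deficitFraction = 0.2} of that mean. All thresholds are printed in
#' reports.
#'
#' The excess threshold controls the family-wise flag rate over the whole
#' map: with the default 100-node grid, a per-node one-sided normal rate of
#' about 2.3e-4 at z = 3.5 keeps the expected number of falsely flagged
#' nodes in a normal sample near 0.02 (a per-node z of 3 would flag some
#' node in roughly one normal sample out of four).
#'
#' @param zHi z-score threshold for excess.
#' @param minExcess occupancy floor for excess flags.
#' @param minFold minimum fold-change of occupancy over the normal mean
#'   (with pseudocount) for an excess flag. Guards against the z-score's
#'   fragility when the per-node sd is estimated from a small donor cohort:
#'   a genuine blast excess is always several-fold above the normal mean,
#'   while sd-underestimation artifacts are not.
#' @param minDeficitBase minimum normal mean occupancy for deficit flags.
#' @param deficitFraction deficit when occupancy < this fraction of the mean.
#' @return named list.
#' @export
compareThresholds <- function(zHi = 3.5, minExcess = 5e-4, minFold = 2,
                              minDeficitBase = 5e-3, deficitFraction = 0.2) {
  list(zHi = zHi, minExcess = minExcess, minFold = minFold,
       minDeficitBase = minDeficitBase, deficitFraction = deficitFraction)
}

#' Compare a mapped sample with normal occupancy ranges
#'
#' Per node: z-score \code{(occupancy - normal mean) / sd} (floored sd from
#' \code{\link{computeNormalRanges}}, so nodes empty in all normals yield
#' large finite z), log2 fold-change with pseudocount
#' \code{1 / eventCount}, and an excess/deficit flag per the thresholds.
#' The summary aggregates total excess burden as percent of all analyzed
#' events in excess-flagged nodes, plus the labels of deficit-flagged nodes.
#'
#' @param mapped a \linkS4class{MappedSample}.
#' @param template the \linkS4class{ReferenceTemplate} it was mapped onto.
#' @param ranges \linkS4class{NormalRanges} derived from the same template.
#' @param thresholds see \code{\link{compareThresholds}}.
#' @return a \linkS4class{ComparisonReport}.
#' @export
compareToReference <- function(mapped, template, ranges,
                               thresholds = compareThresholds()) {
  n <- nNodes(template)
  if (length(mapped@occupancy) != n || length(ranges@mean) != n)
    stop("configuration error: node count mismatch between sample, template and ranges")
  occ <- mapped@occupancy
  z <- (occ - ranges@mean) / ranges@sd
  pseudo <- 1 / max(1L, mapped@eventCount)
  lfc <- log2((occ + pseudo) / (ranges@mean + pseudo))
  minFold <- thresholds$minFold %||% 1
  excess <- z > thresholds$zHi & occ > thresholds$minExcess &
    (occ + pseudo) > minFold * (ranges@mean + pseudo)
  deficit <- ranges@mean > thresholds$minDeficitBase &
    occ < thresholds$deficitFraction * ranges@mean
  flag <- ifelse(excess, "excess", ifelse(deficit, "deficit", "none"))
  labels <- vapply(nodeLabels(template), function(x)
    paste(x, collapse = ";"), "")
  if (!length(labels)) labels <- rep("", n)
  tab <- data.frame(node = seq_len(n), occupancy = occ,
                    normalMean = ranges@mean, normalSd = ranges@sd,
                    z = z, log2fc = lfc, flag = flag, labels = labels)
  deficitLabels <- sort(unique(unlist(
    nodeLabels(template)[which(deficit)])))
  summary <- list(excessBurden = 100 * sum(occ[excess]),
                  excessNodes = which(excess),
                  deficitNodes = which(deficit),
                  deficitLabels = deficitLabels)
  new("ComparisonReport", nodeTable = tab, summary = summary,
      thresholds = thresholds)
}

#' Per-event backgating table
#'
#' One row per event with two measurement channels on the original
#' (untransformed) scale, the event's node id, the node's labels and its
#' comparison flag - the table behind a CD45/SSC display colored by node.
#'
#' @param mapped the \linkS4class{MappedSample} for these events.
#' @param events the raw \linkS4class{EventMatrix} that was mapped.
#' @param template the \linkS4class{ReferenceTemplate}.
#' @param channelX,channelY channel or marker names (e.g. \code{"CD45"},
#'   \code{"SSC"}).
#' @param report optional \linkS4class{ComparisonReport} supplying flags.
#' @return data.frame with columns \code{channelX}, \code{channelY} (named
#'   after the channels), \code{node}, \code{labels}, \code{flag}.
#' @export
backgateTable <- function(mapped, events, template, channelX, channelY,
                          report = NULL) {
  if (nEvents(events) != mapped@eventCount)
    stop("events and mapped sample disagree on event count")
  findCh <- function(name) {
    hit <- which(tolower(colnames(events@exprs)) == tolower(name) |
                 tolower(events@markerNames) == tolower(name))
    if (!length(hit)) stop("unknown channel '", name, "'")
    hit[1]
  }
  ix <- findCh(channelX); iy <- findCh(channelY)
  labels <- vapply(nodeLabels(template), function(x)
    paste(x, collapse = ";"), "")
  if (!length(labels)) labels <- rep("", nNodes(template))
  flag <- rep("none", nNodes(template))
  if (!is.null(report)) flag <- report@nodeTable$flag
  out <- data.frame(events@exprs[, ix], events@exprs[, iy],
                    node = mapped@assignments,
                    labels = labels[mapped@assignments],
                    flag = flag[mapped@assignments])
  names(out)[1:2] <- c(channelX, channelY)
  out
}
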