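#' @include AllClasses.R
NULL

#' Configuration for a reference build
#'
#' @param gridRows,gridCols SOM grid (default 10 x 10 = 100 nodes).
#' @param epochs batch-SOM epochs.
#' @param radiusInitial,radiusFinal neighborhood radius schedule (defaults:
#'   half the grid diagonal down to 0).
#' @param refineEpochs zero-radius refinement epochs with codebook repair
#'   (see \code{\link{trainSOM}}).
#' @param includeForwardScatter include forward scatter in the clustering
#'   space (default: fluorescence + side scatter only).
#' @param preFilter optional row filter applied to the merged events before
#'   analysis (see \code{\link{filterEvents}}); \code{NULL} keeps all events.
#' @return a named list.
#' @export
referenceConfig <- function(gridRows = 10L, gridCols = 10L, epochs = 10L,
                            radiusInitial = NULL, radiusFinal = 0,
                            refineEpochs = 10L,
                            includeForwardScatter = FALSE, preFilter = NULL) {
  list(gridRows = gridRows, gridCols = gridCols, epochs = epochs,
       radiusInitial = radiusInitial, radiusFinal = radiusFinal,
       refineEpochs = refineEpochs,
       includeForwardScatter = includeForwardScatter, preFilter = preFilter)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

## Shared preprocessing path: compensate (if the panel has spillover),
## transform, select+scale. Used identically for reference building (stats
## computed, frozen) and for patient mapping (frozen stats applied), so a
## constituent sample re-mapped through its own template reproduces its
## stored occupancy row exactly.
.preprocessEvents <- function(events, panel, stats = NULL,
                              includeForwardScatter = FALSE) {
  if (length(panel@spillover) && eventState(events) == "raw")
    events <- compensate(events, panel)
  events <- transformEvents(events, panel)
  selectAndScale(events, panel, stats = stats,
                 includeForwardScatter = includeForwardScatter)
}

#' Build a frozen per-panel reference template
#'
#' The merged-normal reference pipeline: merge samples, compensate,
#' arcsinh-transform, select the clustering channels (fluorescence + side
#' scatter) and scale (statistics computed on the merged data and frozen),
#' train the batch SOM, build and lay out the MST, then compute merged
#' node statistics, per-marker phenotype bin edges, and one occupancy row
#' per constituent sample by mapping each raw sample through the finished
#' template. Deterministic given the seed.
#'
#' @param samples list of raw \linkS4class{EventMatrix} objects (the normal
#'   cohort; at least 2, ideally many more).
#' @param panel a \linkS4class{PanelDefinition}.
#' @param config see \code{\link{referenceConfig}}.
#' @param seed master seed (recorded in provenance).
#' @return a \linkS4class{ReferenceTemplate}.
#' @export
buildReference <- function(samples, panel, config = referenceConfig(),
                           seed = 1L) {
  if (length(samples) < 2L)
    stop("input error: at least 2 normal samples required")
  if (length(samples) < 5L)
    warning("fewer than 5 normal samples; occupancy ranges will be unstable")
  merged <- .stage("merge", mergeEvents(samples, panel))
  if (!is.null(config$preFilter))
    merged <- .stage("pre-filter", filterEvents(merged, config$preFilter))
  ss <- .stage("preprocess",
               .preprocessEvents(merged, panel,
                                 includeForwardScatter = config$includeForwardScatter))
  model <- .stage("train-som",
    trainSOM(ss$events, gridRows = config$gridRows, gridCols = config$gridCols,
             epochs = config$epochs, radiusInitial = config$radiusInitial,
             radiusFinal = config$radiusFinal,
             refineEpochs = config$refineEpochs %||% 10L, seed = seed,
             scaling = ss$stats))
  tree <- .stage("mst", buildLayoutMST(model, seed = seed))
  assignments <- .stage("assign", assignBMU(ss$events, model))

  transformed <- .stage("transform-stats", {
    tmp <- merged
    if (length(panel@spillover)) tmp <- compensate(tmp, panel)
    transformEvents(tmp, panel)
  })
  nstats <- .stage("node-stats",
                   computeNodeStats(transformed, assignments, model, panel))
  keep <- ss$stats@channels
  breaks <- t(apply(transformed@exprs[, keep, drop = FALSE], 2,
                    stats::quantile, probs = c(0.2, 0.5, 0.8), names = FALSE))
  colnames(breaks) <- c("q20", "q50", "q80")
  markers <- panel@channels$marker[match(keep, panel@channels$channel)]
  rownames(breaks) <- ifelse(nzchar(markers), markers, keep)

  template <- new("ReferenceTemplate", panel = panel, model = model,
                  tree = tree, nodeStats = nstats,
                  occupancy = matrix(numeric(0), 0, nNodes(model)),
                  markerBreaks = breaks,
                  nodeLabels = rep(list(character(0)), nNodes(model)),
                  provenance = list(
                    sampleIds = vapply(seq_along(samples), function(s)
                      .sampleLabel(samples[[s]], s), ""),
                    seed = seed, nEvents = nEvents(merged),
                    panel = panel@name,
                    version = as.character(utils::packageVersion("marrowSOM"))))

  occ <- .stage("occupancy", {
    rows <- lapply(samples, function(s) occupancy(mapSample(template, s)))
    m <- do.call(rbind, rows)
    rownames(m) <- template@provenance$sampleIds
    m
  })
  template@occupancy <- occ
  methods::validObject(template)
  template
}

#' Node-level statistics
#'
#' Counts and percentages per node over all grid nodes (empty nodes report
#' zero), with per-channel median and mean intensities in transformed space
#' and the medians back-transformed to the measurement scale. Percentages
#' are over all input events.
#'
#' @param events the \linkS4class{EventMatrix} in \code{"transformed"} state.
#' @param assignments per-event node id (from \code{\link{assignBMU}}).
#' @param model the \linkS4class{SOMModel}.
#' @param panel the \linkS4class{PanelDefinition} (for back-transforms).
#' @return data.frame with one row per node: \code{node}, \code{count},
#'   \code{pct}, then \code{med_}, \code{mean_} and \code{medRaw_} columns
#'   per clustering channel (NA for empty nodes).
#' @export
computeNodeStats <- function(events, assignments, model, panel) {
  if (length(assignments) != nEvents(events))
    stop("assignments length must equal event count")
  n <- nNodes(model)
  keep <- model@scaling@channels
  if (!length(keep)) keep <- colnames(events@exprs)
  v <- events@exprs[, keep, drop = FALSE]
  counts <- tabulate(assignments, nbins = n)
  total <- length(assignments)
  f <- factor(assignments, levels = seq_len(n))
  med <- apply(v, 2, function(col) tapply(col, f, stats::median))
  mea <- apply(v, 2, function(col) tapply(col, f, mean))
  if (n == 1L) { med <- matrix(med, 1); mea <- matrix(mea, 1) }
  ch <- panel@channels
  cof <- ch$cofactor[match(keep, ch$channel)]
  kind <- ch$transform[match(keep, ch$channel)]
  medRaw <- med
  for (j in seq_along(keep))
    if (!is.na(kind[j]) && kind[j] == "arcsinh")
      medRaw[, j] <- sinh(med[, j]) * cof[j]
  out <- data.frame(node = seq_len(n), count = counts,
                    pct = if (total > 0) 100 * counts / total else rep(0, n))
  colnames(med) <- paste0("med_", keep)
  colnames(mea) <- paste0("mean_", keep)
  colnames(medRaw) <- paste0("medRaw_", keep)
  cbind(out, med, mea, medRaw)
}

#' Normal occupancy ranges
#'
#' Per-node mean, floored standard deviation, min and max of the occupancy
#' fractions across the normal cohort. The default floor, 1 / (total merged
#' events), keeps z-scores finite for nodes empty in all normals.
#'
#' With a typical cohort of ~19 donors the raw per-node sd estimates carry
#' substantial sampling error (CV about 17 percent), so nodes whose sd
#' happens to be underestimated would flag recurrently in perfectly normal
#' samples. By default the per-node variances are therefore moderated by
#' empirical-Bayes shrinkage toward a mean-occupancy variance trend
#' (\code{limma::squeezeVar}), the standard remedy for exactly this
#' few-replicates variance-estimation problem.
#'
#' @param template a \linkS4class{ReferenceTemplate}.
#' @param sdFloor positive floor on the per-node sd; default
#'   \code{1 / provenance$nEvents}.
#' @param moderate shrink per-node variances toward the trend (default TRUE;
#'   disable for the raw cohort sds).
#' @return a \linkS4class{NormalRanges}.
#' @export
computeNormalRanges <- function(template, sdFloor = NULL, moderate = TRUE) {
  occ <- template@occupancy
  if (nrow(occ) == 0L) stop("input error: empty occupancy matrix")
  if (is.null(sdFloor))
    sdFloor <- 1 / max(1L, template@provenance$nEvents %||% 1L)
  stopifnot(sdFloor > 0)
  mu <- colMeans(occ)
  if (nrow(occ) < 2L) {
    warning("single occupancy row: all sds set to the floor")
    sdv <- rep(sdFloor, ncol(occ))
  } else {
    sdv <- apply(occ, 2, stats::sd)
    if (moderate && ncol(occ) >= 10L) {
      v <- pmax(sdv^2, sdFloor^2)
      sq <- limma::squeezeVar(v, df = nrow(occ) - 1L,
                              covariate = log(mu + sdFloor))
      sdv <- sqrt(sq$var.post)
    }
    sdv <- pmax(sdv, sdFloor)
  }
  new("NormalRanges", mean = unname(mu), sd = unname(sdv),
      min = unname(apply(occ, 2, min)), max = unname(apply(occ, 2, max)),
      sdFloor = sdFloor)
}

## ---- template persistence (directory bundle of plain-text files) ----

#' Save / load a reference template
#'
#' The template is persisted as a directory bundle of plain-text files
#' (CSV tables at full double precision plus JSON for panel, labels and
#' provenance), so rebuilds with identical inputs and seed serialize
#' byte-identically and loading reproduces the template exactly.
#'
#' @param template a \linkS4class{ReferenceTemplate}.
#' @param dir bundle directory (created if needed).
#' @return \code{saveTemplate}: \code{dir}, invisibly. \code{loadTemplate}:
#'   the reconstructed \linkS4class{ReferenceTemplate}.
#' @export
saveTemplate <- function(template, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  writeMatrixExact(template@model@codebook, p("codebook.csv"))
  sc <- template@model@scaling
  writeTableExact(data.frame(channel = sc@channels, location = sc@location,
                             spread = sc@spread), p("scaling.csv"))
  writeTableExact(template@tree@edges, p("mst_edges.csv"))
  lay <- template@tree@layout
  writeTableExact(data.frame(node = seq_len(nrow(lay)), x = lay[, 1],
                             y = lay[, 2]), p("layout.csv"))
  writeTableExact(template@nodeStats, p("node_stats.csv"))
  writeMatrixExact(template@occupancy, p("occupancy.csv"))
  writeMatrixExact(template@markerBreaks, p("marker_breaks.csv"))
  ch <- template@panel@channels
  panelList <- list(name = template@panel@name, channels = ch,
                    spillover = if (length(template@panel@spillover))
                      list(channels = colnames(template@panel@spillover) %||%
                             ch$channel[ch$role == "fluorescence"],
                           values = apply(template@panel@spillover, 1, fmtNum,
                                          simplify = FALSE)) else NULL)
  jsonlite::write_json(panelList, p("panel.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  jsonlite::write_json(template@nodeLabels, p("node_labels.json"),
                       auto_unbox = FALSE)
  m <- template@model@meta
  jsonlite::write_json(list(gridRows = template@model@gridRows,
                            gridCols = template@model@gridCols,
                            meta = m), p("model_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(template@provenance, p("provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname saveTemplate
#' @export
loadTemplate <- function(dir) {
  p <- function(f) file.path(dir, f)
  panelList <- jsonlite::read_json(p("panel.json"), simplifyVector = TRUE)
  spill <- NULL
  if (!is.null(panelList$spillover)) {
    vals <- panelList$spillover$values
    spill <- do.call(rbind, lapply(vals, as.numeric))
    rownames(spill) <- colnames(spill) <- panelList$spillover$channels
  }
  panel <- panelDefinition(panelList$name,
                           as.data.frame(panelList$channels), spill)
  sc <- readTableExact(p("scaling.csv"))
  scaling <- new("ScalingStats", channels = as.character(sc$channel),
                 location = sc$location, spread = sc$spread)
  mm <- jsonlite::read_json(p("model_meta.json"), simplifyVector = TRUE)
  model <- new("SOMModel", gridRows = as.integer(mm$gridRows),
               gridCols = as.integer(mm$gridCols),
               codebook = readMatrixExact(p("codebook.csv")),
               scaling = scaling, meta = as.list(mm$meta))
  edges <- readTableExact(p("mst_edges.csv"))
  lay <- readTableExact(p("layout.csv"))
  tree <- new("MSTGraph", nNodes = nNodes(model),
              edges = data.frame(from = as.integer(edges$from),
                                 to = as.integer(edges$to),
                                 weight = edges$weight),
              layout = cbind(lay$x, lay$y))
  labels <- jsonlite::read_json(p("node_labels.json"))
  labels <- lapply(labels, function(x) as.character(unlist(x)))
  new("ReferenceTemplate", panel = panel, model = model, tree = tree,
      nodeStats = readTableExact(p("node_stats.csv")),
      occupancy = local({
        m <- readMatrixExact(p("occupancy.csv"))
        colnames(m) <- NULL
        m
      }),
      markerBreaks = readMatrixExact(p("marker_breaks.csv")),
      nodeLabels = labels,
      provenance = jsonlite::read_json(p("provenance.json"),
                                       simplifyVector = TRUE))
}
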