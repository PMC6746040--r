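#' @include AllClasses.R
NULL

#' Compensate fluorescence spillover
#'
#' Replaces the fluorescence columns by \code{observed \%*\% solve(spillover)}
#' (rows of the spillover matrix are source stains, columns detectors).
#' Scatter and time columns are untouched.
#'
#' @param events an \linkS4class{EventMatrix} in \code{"raw"} state, columns
#'   in panel order (see \code{\link{mergeEvents}}).
#' @param panel a \linkS4class{PanelDefinition} with a spillover matrix.
#' @return the compensated \linkS4class{EventMatrix}.
#' @export
compensate <- function(events, panel) {
  if (eventState(events) != "raw")
    stop("compensate expects raw events, got state '", eventState(events), "'")
  sp <- panel@spillover
  if (!length(sp)) stop("panel '", panel@name, "' has no spillover matrix")
  fluor <- panel@channels$channel[panel@channels$role == "fluorescence"]
  if (nrow(sp) != length(fluor))
    stop("spillover dimension does not match fluorescence channel count")
  if (qr(sp)$rank < nrow(sp))
    stopWithClass("marrowSOM_singular_spillover",
                  "spillover matrix for panel '%s' is singular", panel@name)
  inv <- solve(sp)
  v <- events@exprs
  v[, fluor] <- v[, fluor, drop = FALSE] %*% inv
  methods::initialize(events, exprs = v, state = "compensated")
}

.transformSpec <- function(panel) {
  ch <- panel@channels
  list(channel = ch$channel, kind = ch$transform, cofactor = ch$cofactor)
}

#' Arcsinh-transform fluorescence and side scatter
#'
#' Applies \code{asinh(x / cofactor)} per channel whose transform kind is
#' \code{"arcsinh"} (by default all fluorescence channels, cofactor 150, and
#' side scatter, cofactor 10000); identity channels (forward scatter, time)
#' are untouched. Monotone and invertible (\code{\link{inverseTransformEvents}}).
#'
#' @param events an \linkS4class{EventMatrix} in \code{"compensated"} state
#'   (or \code{"raw"} for panels without spillover).
#' @param panel a \linkS4class{PanelDefinition}.
#' @return the transformed \linkS4class{EventMatrix}.
#' @export
transformEvents <- function(events, panel) {
  st <- eventState(events)
  if (!(st %in% c("compensated", "raw")))
    stop("transformEvents expects compensated (or raw) events, got '", st, "'")
  if (st == "raw" && length(panel@spillover))
    stop("panel declares a spillover matrix; compensate before transforming")
  ts <- .transformSpec(panel)
  if (any(ts$cofactor <= 0))
    stop("configuration error: non-positive transform cofactor")
  v <- events@exprs
  for (i in seq_along(ts$channel)) {
    if (ts$kind[i] == "arcsinh" && ts$channel[i] %in% colnames(v))
      v[, ts$channel[i]] <- asinh(v[, ts$channel[i]] / ts$cofactor[i])
  }
  methods::initialize(events, exprs = v, state = "transformed")
}

#' @rdname transformEvents
#' @export
inverseTransformEvents <- function(events, panel) {
  if (eventState(events) != "transformed")
    stop("inverseTransformEvents expects transformed events")
  ts <- .transformSpec(panel)
  v <- events@exprs
  for (i in seq_along(ts$channel)) {
    if (ts$kind[i] == "arcsinh" && ts$channel[i] %in% colnames(v))
      v[, ts$channel[i]] <- sinh(v[, ts$channel[i]]) * ts$cofactor[i]
  }
  methods::initialize(events, exprs = v, state = "compensated")
}

#' Select clustering channels and scale into SOM space
#'
#' Retains all fluorescence channels plus side scatter (forward scatter and
#' time are excluded by default), then standardizes each retained channel.
#' With \code{stats = NULL} the per-channel median (location) and standard
#' deviation (spread, floored at \code{spreadFloor}) are computed from the
#' data and returned - reference-building mode. With \code{stats} supplied
#' they are applied unchanged - mapping mode, guaranteeing that patient
#' samples land in the reference's coordinate system.
#'
#' @param events an \linkS4class{EventMatrix} in \code{"transformed"} state.
#' @param panel a \linkS4class{PanelDefinition}.
#' @param stats a frozen \linkS4class{ScalingStats}, or \code{NULL} to
#'   compute from the data.
#' @param includeForwardScatter also retain forward scatter.
#' @param spreadFloor lower bound on the per-channel spread.
#' @return list with \code{events} (state \code{"scaled"}) and \code{stats}.
#' @export
selectAndScale <- function(events, panel, stats = NULL,
                           includeForwardScatter = FALSE,
                           spreadFloor = 1e-6) {
  if (eventState(events) != "transformed")
    stop("selectAndScale expects transformed events, got '",
         eventState(events), "'")
  keep <- clusteringChannels(panel, includeForwardScatter)
  missing <- setdiff(keep, colnames(events@exprs))
  if (length(missing))
    stopWithClass("marrowSOM_channel_mismatch",
                  "channels absent from events: %s", paste(missing, collapse = ", "))
  v <- events@exprs[, keep, drop = FALSE]
  if (is.null(stats)) {
    loc <- apply(v, 2, stats::median)
    spr <- apply(v, 2, stats::sd)
    if (nrow(v) < 2L) spr[] <- NA_real_
    flat <- !is.finite(spr) | spr < spreadFloor
    if (any(flat)) {
      warning("constant (or near-constant) channel(s) floored: ",
              paste(keep[flat], collapse = ", "))
      spr[flat] <- spreadFloor
    }
    stats <- new("ScalingStats", channels = keep, location = unname(loc),
                 spread = unname(spr))
  } else {
    if (!identical(stats@channels, keep))
      stop("configuration error: scaling stats channel order does not match panel")
  }
  v <- sweep(v, 2, stats@location, "-")
  v <- sweep(v, 2, stats@spread, "/")
  scaled <- methods::initialize(events, exprs = v, state = "scaled",
                                markerNames = panel@channels$marker[
                                  match(keep, panel@channels$channel)])
  list(events = scaled, stats = stats)
}
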