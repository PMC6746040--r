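#' @include AllClasses.R
NULL

## Squared Euclidean distances events x codebook, via the expansion
## |x|^2 + |c|^2 - 2 x.c (clamped at 0 for numerical noise).
.dist2 <- function(x, cb) {
  d2 <- outer(rowSums(x^2), rowSums(cb^2), "+") - 2 * tcrossprod(x, cb)
  d2[d2 < 0] <- 0
  d2
}

.bmuOf <- function(x, cb, block = 50000L) {
  n <- nrow(x)
  out <- integer(n)
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(n, start + block - 1L)
    out[idx] <- max.col(-.dist2(x[idx, , drop = FALSE], cb),
                        ties.method = "first")
  }
  out
}

## best and second-best unit per event, with squared distances
.bmuTwo <- function(x, cb, block = 50000L) {
  n <- nrow(x)
  bmu <- integer(n); d2own <- numeric(n); d2alt <- numeric(n)
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(n, start + block - 1L)
    d2 <- .dist2(x[idx, , drop = FALSE], cb)
    o1 <- max.col(-d2, ties.method = "first")
    rows <- seq_along(idx)
    d1 <- d2[cbind(rows, o1)]
    d2[cbind(rows, o1)] <- Inf
    o2 <- max.col(-d2, ties.method = "first")
    bmu[idx] <- o1
    d2own[idx] <- d1
    d2alt[idx] <- d2[cbind(rows, o2)]
  }
  list(bmu = bmu, d2own = d2own, d2alt = d2alt)
}

## ELBG-style utility reallocation: relocate the node whose removal is
## cheapest (its events fall back to their second-best unit) into the
## highest-distortion cluster, seeding it at that cluster's farthest
## member. A move is applied only when the exactly computed SSE gain
## exceeds the exact cost, so the quantization error never increases.
.reallocateNodes <- function(x, cb, maxMoves = 2L) {
  nNodes <- nrow(cb)
  for (mv in seq_len(maxMoves)) {
    nb <- .bmuTwo(x, cb)
    sse <- rep(0, nNodes)
    agg <- rowsum(nb$d2own, group = nb$bmu)
    sse[as.integer(rownames(agg))] <- agg
    cost <- rep(0, nNodes)
    aggc <- rowsum(nb$d2alt - nb$d2own, group = nb$bmu)
    cost[as.integer(rownames(aggc))] <- aggc
    donors <- order(cost)
    accepted <- FALSE
    # a high-SSE but diffuse cluster can gain little from splitting while
    # a smaller bimodal one gains a lot, so try targets in SSE order
    for (target in utils::head(order(sse, decreasing = TRUE), 10L)) {
      donor <- donors[1]
      if (donor == target) donor <- donors[2]
      members <- which(nb$bmu == target)
      if (!length(members)) next
      ## candidate split positions: members across the upper half of the
      ## within-cluster distance distribution (the farthest member alone is
      ## often a stray outlier that captures nothing; a candidate inside a
      ## secondary mode realizes the bimodal split)
      ord <- members[order(nb$d2own[members])]
      qs <- unique(pmax(1L, round(seq(0.5, 1, length.out = 24) *
                                    length(ord))))
      xm <- x[members, , drop = FALSE]
      best <- 0; bestpos <- NULL
      for (cand in ord[qs]) {
        d2new <- rowSums(sweep(xm, 2, x[cand, ], "-")^2)
        gain <- sum(pmax(0, nb$d2own[members] - d2new))
        if (gain > best) {
          best <- gain
          bestpos <- x[cand, ]
        }
      }
      if (best > cost[donor] + 1e-9) {
        cb[donor, ] <- bestpos
        accepted <- TRUE
        break
      }
    }
    if (!accepted) break
  }
  cb
}

.gridCoords <- function(rows, cols) {
  ## 1-based node ids in row-major order
  cbind(row = rep(seq_len(rows), each = cols),
        col = rep(seq_len(cols), times = rows))
}

## Chebyshev distance between grid positions (rectangular topology).
.gridDistance <- function(rows, cols) {
  g <- .gridCoords(rows, cols)
  dr <- abs(outer(g[, 1], g[, 1], "-"))
  dc <- abs(outer(g[, 2], g[, 2], "-"))
  pmax(dr, dc)
}

#' Train a batch self-organizing map
#'
#' Batch Kohonen SOM on a rectangular grid: the codebook is initialized by
#' seeded random sampling of events; each epoch assigns every event to its
#' best-matching unit and then replaces every codebook vector by the
#' Gaussian-neighborhood-weighted mean of the events assigned to nearby
#' units, with the neighborhood radius shrinking linearly from
#' \code{radiusInitial} to \code{radiusFinal} over the epochs. Batch mode is
#' deterministic given the seed and independent of event order.
#'
#' @param events an \linkS4class{EventMatrix} in \code{"scaled"} state, or a
#'   plain numeric matrix in scaled space.
#' @param gridRows,gridCols grid dimensions; the 10 x 10 default realizes a
#'   100-node map.
#' @param epochs number of batch epochs.
#' @param radiusInitial initial neighborhood radius (grid Chebyshev units);
#'   default half the grid diagonal.
#' @param radiusFinal final radius; the default 0 makes the last scheduled
#'   epoch a plain quantization (k-means) step, letting nodes specialize.
#' @param seed RNG seed for codebook initialization (recorded in the model).
#' @param scaling optional \linkS4class{ScalingStats} to freeze into the
#'   model.
#' @param refineEpochs additional zero-radius refinement epochs appended
#'   after the schedule (only when \code{radiusFinal} is 0).
#' @param reseedEmpty during refinement, repair the codebook by utility
#'   reallocation (enhanced-LBG style): the node whose removal costs least
#'   is relocated into the highest-distortion cluster whenever the exact
#'   SSE gain exceeds the exact cost. Deterministic; never increases the
#'   quantization error, and lets rare well-separated populations acquire
#'   dedicated nodes instead of sharing one with a neighbor.
#' @return a \linkS4class{SOMModel}.
#' @export
trainSOM <- function(events, gridRows = 10L, gridCols = 10L, epochs = 10L,
                     radiusInitial = NULL, radiusFinal = 0, seed = 1L,
                     scaling = NULL, refineEpochs = 10L, reseedEmpty = TRUE) {
  x <- if (is(events, "EventMatrix")) {
    if (eventState(events) != "scaled")
      stop("trainSOM expects scaled events, got '", eventState(events), "'")
    events@exprs
  } else as.matrix(events)
  if (nrow(x) == 0L) stop("input error: empty event set")
  gridRows <- as.integer(gridRows); gridCols <- as.integer(gridCols)
  stopifnot(gridRows >= 1L, gridCols >= 1L, epochs >= 1L)
  nNodes <- gridRows * gridCols
  if (nrow(x) < nNodes)
    warning("fewer events (", nrow(x), ") than nodes (", nNodes, ")")
  if (is.null(radiusInitial))
    radiusInitial <- sqrt((gridRows - 1)^2 + (gridCols - 1)^2) / 2
  radiusInitial <- max(radiusInitial, radiusFinal)

  init <- withSeed(seed, sample.int(nrow(x), nNodes, replace = nrow(x) < nNodes))
  cb <- x[init, , drop = FALSE]
  rownames(cb) <- NULL
  gridD <- .gridDistance(gridRows, gridCols)

  total <- epochs + if (radiusFinal <= 1e-9) max(0L, as.integer(refineEpochs)) else 0L
  for (e in seq_len(total)) {
    radius <- if (e >= epochs) radiusFinal
      else if (epochs == 1L) radiusFinal
      else radiusInitial + (radiusFinal - radiusInitial) * (e - 1) / (epochs - 1)
    ## codebook repair (refinement phase only): empty or low-utility nodes
    ## migrate into the highest-distortion clusters (see .reallocateNodes)
    if (reseedEmpty && radius <= 1e-9 && e > epochs && nNodes > 1L)
      cb <- .reallocateNodes(x, cb)
    bmu <- .bmuOf(x, cb)
    counts <- tabulate(bmu, nbins = nNodes)
    sums <- matrix(0, nNodes, ncol(x))
    sums[sort(unique(bmu)), ] <- rowsum(x, group = bmu)  # sorted by group
    H <- if (radius > 1e-9) exp(-gridD^2 / (2 * radius^2)) else diag(nNodes)
    den <- as.vector(H %*% counts)
    num <- H %*% sums
    upd <- den > 1e-12
    cb[upd, ] <- num[upd, , drop = FALSE] / den[upd]
  }
  if (is.null(scaling))
    scaling <- new("ScalingStats",
                   channels = colnames(x) %||% paste0("ch", seq_len(ncol(x))),
                   location = numeric(ncol(x)), spread = rep(1, ncol(x)))
  colnames(cb) <- colnames(x)
  new("SOMModel", gridRows = gridRows, gridCols = gridCols, codebook = cb,
      scaling = scaling,
      meta = list(epochs = as.integer(epochs), radiusInitial = radiusInitial,
                  radiusFinal = radiusFinal, schedule = "linear", seed = seed))
}

#' Assign events to their best-matching unit
#'
#' Each event is mapped to the node (1-based id) whose codebook vector is
#' nearest in Euclidean distance; exact ties break toward the lowest node id.
#'
#' @param events scaled \linkS4class{EventMatrix} or plain matrix with the
#'   model's channel order.
#' @param model a \linkS4class{SOMModel}.
#' @return integer vector of node ids, one per event.
#' @export
assignBMU <- function(events, model) {
  x <- if (is(events, "EventMatrix")) events@exprs else as.matrix(events)
  cb <- model@codebook
  if (ncol(x) != ncol(cb))
    stop("configuration error: event channel count does not match codebook")
  if (!is.null(colnames(x)) && !is.null(colnames(cb)) &&
      !identical(colnames(x), colnames(cb)))
    stop("configuration error: channel order does not match model scaling")
  .bmuOf(x, cb)
}

#' Mean quantization error
#'
#' Mean Euclidean distance of events to their best-matching unit; the
#' batch-SOM objective tracked across epochs.
#'
#' @inheritParams assignBMU
#' @return a single number.
#' @export
quantizationError <- function(events, model) {
  x <- if (is(events, "EventMatrix")) events@exprs else as.matrix(events)
  d2 <- .dist2(x, model@codebook)
  mean(sqrt(d2[cbind(seq_len(nrow(x)), max.col(-d2, ties.method = "first"))]))
}

#' Group nodes into metaclusters
#'
#' Average-linkage agglomerative clustering of the codebook vectors, cut at
#' \code{k} groups. Deterministic; offered as an aid to expert node review,
#' not a replacement for it.
#'
#' @param model a \linkS4class{SOMModel}.
#' @param k number of metaclusters, between 1 and the node count.
#' @return integer vector mapping node id to metacluster id.
#' @export
metacluster <- function(model, k) {
  n <- nrow(model@codebook)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > n)
    stop("input error: k must be between 1 and the node count (", n, ")")
  hc <- stats::hclust(stats::dist(model@codebook), method = "average")
  stats::cutree(hc, k = as.integer(k))
}
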