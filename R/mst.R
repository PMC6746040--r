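#' @include AllClasses.R
NULL

#' Build the minimal spanning tree over SOM nodes
#'
#' Minimum spanning tree of the complete graph over codebook vectors with
#' Euclidean edge weights in scaled space. Edges are returned with
#' \code{from < to}, sorted lexicographically.
#'
#' @param model a \linkS4class{SOMModel} (or a \linkS4class{ReferenceTemplate}).
#' @return an \linkS4class{MSTGraph} (layout empty; see \code{\link{layoutMST}}).
#' @export
buildMST <- function(model) {
  if (is(model, "ReferenceTemplate")) model <- model@model
  cb <- model@codebook
  n <- nrow(cb)
  if (n < 1L) stop("empty model")
  if (n == 1L)
    return(new("MSTGraph", nNodes = 1L,
               edges = data.frame(from = integer(0), to = integer(0),
                                  weight = numeric(0)),
               layout = matrix(numeric(0), 0, 2)))
  pairs <- t(utils::combn(n, 2L))
  w <- as.vector(stats::dist(cb))  # same pair order as combn(n, 2)
  g <- igraph::graph_from_edgelist(pairs, directed = FALSE)
  igraph::E(g)$weight <- w
  tr <- igraph::mst(g, algorithm = "prim")
  el <- igraph::as_edgelist(tr, names = FALSE)
  ew <- igraph::E(tr)$weight
  from <- pmin(el[, 1], el[, 2])
  to <- pmax(el[, 1], el[, 2])
  o <- order(from, to)
  new("MSTGraph", nNodes = as.integer(n),
      edges = data.frame(from = as.integer(from[o]), to = as.integer(to[o]),
                         weight = ew[o]),
      layout = matrix(numeric(0), 0, 2))
}

#' Lay out an MST in two dimensions
#'
#' Seeded force-directed (Fruchterman-Reingold) embedding of the tree.
#' Deterministic given the seed; coordinates are finite and pairwise
#' distinct (coincident points are separated by a deterministic nudge).
#'
#' @param tree an \linkS4class{MSTGraph}.
#' @param seed RNG seed.
#' @return nodes x 2 coordinate matrix.
#' @export
layoutMST <- function(tree, seed = 1L) {
  n <- tree@nNodes
  if (n == 1L) return(matrix(c(0, 0), 1, 2))
  g <- igraph::graph_from_edgelist(as.matrix(tree@edges[, c("from", "to")]),
                                   directed = FALSE)
  coords <- withSeed(seed,
    igraph::layout_with_fr(g, weights = rep(1, nrow(tree@edges))))
  dup <- duplicated(round(coords, 9))
  if (any(dup)) {
    k <- which(dup)
    coords[k, 1] <- coords[k, 1] + 1e-6 * seq_along(k)
  }
  unname(coords[, 1:2, drop = FALSE])
}

#' @rdname layoutMST
#' @param model optional; convenience that builds and lays out in one call.
#' @export
buildLayoutMST <- function(model, seed = 1L) {
  tr <- buildMST(model)
  tr@layout <- layoutMST(tr, seed = seed)
  tr
}
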