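## Independent oracles used by unit and acceptance tests.

modelFromCodebook <- function(cb, rows = nrow(cb), cols = 1L) {
  new("SOMModel", gridRows = as.integer(rows), gridCols = as.integer(cols),
      codebook = cb,
      scaling = new("ScalingStats", channels = character(0),
                    location = numeric(0), spread = numeric(0)),
      meta = list(seed = 1))
}

# total weight of the minimum labelled spanning tree by exhaustive
# enumeration over Pruefer sequences (n^(n-2) trees)
bruteForceMSTWeight <- function(d) {
  n <- nrow(d)
  if (n == 2) return(d[1, 2])
  pruefer <- as.matrix(do.call(expand.grid,
                               rep(list(seq_len(n)), n - 2)))
  best <- Inf
  for (r in seq_len(nrow(pruefer))) {
    seqv <- pruefer[r, ]
    degree <- rep(1L, n)
    for (v in seqv) degree[v] <- degree[v] + 1L
    w <- 0
    deg <- degree
    avail <- rep(TRUE, n)
    s <- seqv
    for (v in s) {
      leaf <- which(avail & deg == 1L)[1]
      w <- w + d[leaf, v]
      deg[leaf] <- 0L
      avail[leaf] <- FALSE
      deg[v] <- deg[v] - 1L
    }
    last <- which(avail & deg == 1L)
    w <- w + d[last[1], last[2]]
    best <- min(best, w)
  }
  best
}

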