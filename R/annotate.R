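#' @include AllClasses.R
NULL

.LEVELS <- c("neg", "lo", "pos", "hi")

#' Construct a phenotype rule set
#'
#' @param ... rules, each a list with \code{label}, \code{clauses} (named
#'   character vector marker -> level among neg/lo/pos/hi) and optional
#'   \code{priority} (lower = earlier; default 1).
#' @param breaks optional named list of absolute per-marker bin edges
#'   (numeric length 3: neg/lo, lo/pos, pos/hi boundaries on the
#'   transformed scale), overriding the default quantile edges.
#' @return a \linkS4class{PhenotypeRuleSet}.
#' @export
phenotypeRules <- function(..., breaks = list()) {
  rules <- lapply(list(...), function(r) {
    r$priority <- as.integer(r$priority %||% 1L)
    r$clauses <- unlist(r$clauses)
    r
  })
  new("PhenotypeRuleSet", rules = rules, breaks = breaks)
}

#' Read phenotype rules from a YAML or JSON file
#'
#' Expected structure: a top-level \code{rules} list (each entry:
#' \code{label}, \code{clauses} mapping marker to level, optional
#' \code{priority}) and an optional top-level \code{breaks} mapping marker
#' to three ascending bin edges.
#'
#' @param path file path (.yaml/.yml or .json).
#' @return a \linkS4class{PhenotypeRuleSet}.
#' @export
readPhenotypeRules <- function(path) {
  spec <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  rules <- lapply(spec$rules, function(r) {
    list(label = r$label, priority = as.integer(r$priority %||% 1L),
         clauses = unlist(r$clauses))
  })
  breaks <- lapply(spec$breaks %||% list(), function(b) as.numeric(unlist(b)))
  new("PhenotypeRuleSet", rules = rules, breaks = breaks)
}

#' Bundled progenitor rule set (synthetic fixture)
#'
#' Rules delineating the three CD34/CD38 progenitor compartments -
#' CD34+CD38- , CD34+CD38+ and CD34lo CD38+ - with absolute bin edges for
#' CD34 and CD38. The edges are package fixtures chosen for the synthetic
#' marrow model, not values taken from any reference dataset.
#'
#' @return a \linkS4class{PhenotypeRuleSet}.
#' @export
progenitorRules <- function() {
  phenotypeRules(
    list(label = "Ber1", priority = 1L,
         clauses = c(CD34 = "pos", CD38 = "neg")),
    list(label = "Ber2", priority = 2L,
         clauses = c(CD34 = "pos", CD38 = "pos")),
    list(label = "MonoBer", priority = 3L,
         clauses = c(CD34 = "lo", CD38 = "pos")),
    breaks = list(CD34 = c(0.8, 2.2, 3.8), CD38 = c(0.8, 2.0, 3.8)))
}

.markerKey <- function(template) {
  ## clustering channels keyed by marker name where present
  keep <- template@model@scaling@channels
  ch <- template@panel@channels
  markers <- ch$marker[match(keep, ch$channel)]
  stats::setNames(keep, ifelse(nzchar(markers), markers, keep))
}

#' Summarize node phenotypes as neg/lo/pos/hi levels
#'
#' For each clustering marker the merged-data transformed intensity
#' distribution is split at its 20th/50th/80th percentiles (stored in the
#' template at build time) into neg/lo/pos/hi bins; each node's level is the
#' bin of its median. Absolute per-marker edges may override the quantile
#' edges. Empty nodes have undefined (NA) levels.
#'
#' @param template a \linkS4class{ReferenceTemplate}.
#' @param breaks named list of absolute per-marker edges (numeric length 3),
#'   e.g. from a \linkS4class{PhenotypeRuleSet}.
#' @return data.frame: \code{node}, \code{count}, then one level column per
#'   marker (factor-free character among neg/lo/pos/hi, NA when empty).
#' @export
summarizeNodePhenotypes <- function(template, breaks = list()) {
  key <- .markerKey(template)
  ns <- template@nodeStats
  out <- data.frame(node = ns$node, count = ns$count)
  for (marker in names(key)) {
    edges <- breaks[[marker]] %||% unname(template@markerBreaks[marker, ])
    if (length(edges) != 3L || is.unsorted(edges))
      stop("configuration error: bin edges for '", marker,
           "' must be 3 ascending values")
    med <- ns[[paste0("med_", key[[marker]])]]
    lev <- .LEVELS[findInterval(med, edges) + 1L]
    lev[ns$count == 0L] <- NA_character_
    out[[marker]] <- lev
  }
  out
}

.clauseMatches <- function(clauseLevel, nodeLevel) {
  if (is.na(nodeLevel)) return(FALSE)
  switch(clauseLevel,
         pos = nodeLevel %in% c("pos", "hi"),
         hi = nodeLevel == "hi",
         lo = nodeLevel == "lo",
         neg = nodeLevel == "neg",
         FALSE)
}

#' Label nodes by phenotype rules
#'
#' A node receives every label whose clauses all match its phenotype levels
#' (a \code{pos} clause matches pos or hi). Multiple matches are kept,
#' sorted by rule priority, and reported with a warning. Labeling is a pure
#' function of the template statistics and rules.
#'
#' @param template a \linkS4class{ReferenceTemplate}.
#' @param rules a \linkS4class{PhenotypeRuleSet}.
#' @return list (one character vector of labels per node), with the node
#'   phenotype table as attribute \code{"phenotypes"}.
#' @export
labelNodes <- function(template, rules) {
  key <- .markerKey(template)
  for (r in rules@rules) {
    unknown <- setdiff(names(r$clauses), names(key))
    if (length(unknown))
      stop("configuration error: rule '", r$label,
           "' references unknown marker(s): ", paste(unknown, collapse = ", "))
  }
  pheno <- summarizeNodePhenotypes(template, breaks = rules@breaks)
  n <- nrow(pheno)
  labels <- rep(list(character(0)), n)
  prio <- vapply(rules@rules, function(r) r$priority, 1L)
  ord <- order(prio)
  ambiguous <- 0L
  for (i in seq_len(n)) {
    hits <- character(0)
    for (r in rules@rules[ord]) {
      ok <- all(vapply(names(r$clauses), function(m)
        .clauseMatches(r$clauses[[m]], pheno[[m]][i]), TRUE))
      if (ok) hits <- c(hits, r$label)
    }
    if (length(hits) > 1L) ambiguous <- ambiguous + 1L
    labels[[i]] <- hits
  }
  if (ambiguous > 0L)
    warning(ambiguous, " node(s) matched more than one rule (all labels kept)")
  attr(labels, "phenotypes") <- pheno
  labels
}

#' Group labeled nodes
#'
#' For each label, the set of nodes carrying it, and its display grouping:
#' connected components of same-labeled nodes on the MST.
#'
#' @param template a \linkS4class{ReferenceTemplate}.
#' @param labels output of \code{\link{labelNodes}} (default: the template's
#'   stored labels).
#' @return data.frame: \code{label}, \code{nodes} (comma-separated ids),
#'   \code{nNodes}, \code{nComponents}, \code{count} (merged events).
#' @export
labelGroups <- function(template, labels = nodeLabels(template)) {
  labs <- unique(unlist(labels))
  if (!length(labs))
    return(data.frame(label = character(0), nodes = character(0),
                      nNodes = integer(0), nComponents = integer(0),
                      count = integer(0)))
  g <- igraph::graph_from_edgelist(
    as.matrix(template@tree@edges[, c("from", "to")]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, template@tree@nNodes - igraph::vcount(g)))
  counts <- template@nodeStats$count
  do.call(rbind, lapply(labs, function(lb) {
    nodes <- which(vapply(labels, function(x) lb %in% x, TRUE))
    sub <- igraph::induced_subgraph(g, nodes)
    data.frame(label = lb, nodes = paste(nodes, collapse = ","),
               nNodes = length(nodes),
               nComponents = igraph::components(sub)$no,
               count = sum(counts[nodes]))
  }))
}
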