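#' @include AllClasses.R
NULL

## Bundled 10-color + scatter panel fixtures and synthetic normal-marrow
## population tables. All numeric phenotype values here are hand-authored
## synthetic fixtures on the arcsinh scale (fluorescence cofactor 150, SSC
## cofactor 10000), chosen to reproduce the qualitative marker patterns of
## the named marrow subsets; they are not measurements from any dataset.

.PANEL_MARKERS <- list(
  "AML-A" = c("CD45", "CD34", "CD38", "CD13", "CD33", "CD14", "CD16",
              "CD64", "HLA-DR", "CD11b"),
  "AML-B" = c("CD45", "CD34", "CD38", "CD117", "CD13", "CD33", "HLA-DR",
              "CD7", "CD56", "CD19"),
  "ALL-A" = c("CD45", "CD19", "CD10", "CD34", "CD38", "CD20", "CD22",
              "CD58", "CD123", "CD66c"),
  "ALL-B" = c("CD45", "CD19", "CD10", "CD34", "CD38", "CD3", "CD5",
              "CD7", "CD2", "CD56"))

#' Bundled panel definitions
#'
#' Four 10-color + scatter panels (two myeloid, two lymphoid), each with
#' forward scatter, side scatter, ten fluorescence channels (FL1..FL10,
#' arcsinh cofactor 150; SSC cofactor 10000) and a time channel, plus a
#' banded synthetic spillover matrix (4% adjacent, 1% next-adjacent
#' bleed-through).
#'
#' @param name one of \code{"AML-A"}, \code{"AML-B"}, \code{"ALL-A"},
#'   \code{"ALL-B"}.
#' @return a \linkS4class{PanelDefinition} with 13 channels, of which 11
#'   (10 fluorescence + SSC) enter the clustering space.
#' @export
bmPanel <- function(name = c("AML-B", "AML-A", "ALL-A", "ALL-B")) {
  name <- match.arg(name)
  markers <- .PANEL_MARKERS[[name]]
  nf <- length(markers)
  channels <- data.frame(
    channel = c("FSC", "SSC", paste0("FL", seq_len(nf)), "TIME"),
    marker = c("", "SSC", markers, ""),
    role = c("forward_scatter", "side_scatter",
             rep("fluorescence", nf), "time"),
    stringsAsFactors = FALSE)
  spill <- diag(nf)
  for (i in seq_len(nf)) for (j in seq_len(nf)) {
    if (abs(i - j) == 1) spill[i, j] <- 0.04
    if (abs(i - j) == 2) spill[i, j] <- 0.01
  }
  dimnames(spill) <- list(paste0("FL", seq_len(nf)), paste0("FL", seq_len(nf)))
  panelDefinition(name, channels, spill)
}

## One population row: unspecified markers default to the negative level.
.pop <- function(name, freq, ssc, sdFluor = 0.30, sdSSC = 0.15, ...) {
  list(name = name, freq = freq, ssc = ssc, sdFluor = sdFluor,
       sdSSC = sdSSC, means = c(...))
}

.popsToSpec <- function(pops, markers, negLevel = 0.30) {
  rows <- lapply(pops, function(p) {
    m <- rep(negLevel, length(markers))
    names(m) <- markers
    known <- intersect(names(p$means), markers)
    m[known] <- p$means[known]
    c(list(population = p$name, frequency = p$freq),
      as.list(stats::setNames(m, paste0("mean.", markers))),
      list(mean.SSC = p$ssc),
      as.list(stats::setNames(rep(p$sdFluor, length(markers)),
                              paste0("sd.", markers))),
      list(sd.SSC = p$sdSSC))
  })
  df <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, check.names = FALSE)))
  rownames(df) <- NULL
  df
}

## Remaining frequency mass goes to the first (dominant) population so the
## table sums to 1 exactly.
.fillDominant <- function(pops) {
  rest <- sum(vapply(pops[-1], function(p) p$freq, 1))
  pops[[1]]$freq <- 1 - rest
  pops
}

.POPS <- list(
  "AML-B" = list(
    .pop("Gran", NA, 2.7, CD45 = 2.2, CD13 = 3.0, CD33 = 1.5, CD38 = 1.0),
    .pop("IG2", 0.040, 2.5, CD45 = 1.9, CD13 = 2.6, CD33 = 2.6, CD38 = 1.5),
    .pop("IG1", 0.030, 2.3, CD45 = 1.7, CD13 = 1.8, CD33 = 3.0, CD38 = 2.0),
    .pop("PrMy", 0.020, 2.2, CD45 = 1.8, CD117 = 3.0, CD13 = 2.8,
         CD33 = 3.0, CD38 = 3.0),
    .pop("ProGR", 0.015, 1.8, CD45 = 1.8, CD117 = 2.6, CD38 = 3.0,
         CD33 = 2.6, "HLA-DR" = 2.2, CD34 = 0.4),
    .pop("Mo", 0.070, 1.9, CD45 = 3.4, CD33 = 3.8, CD13 = 2.6, CD38 = 2.4,
         "HLA-DR" = 3.0),
    .pop("Mo3", 0.008, 1.8, CD45 = 3.6, CD33 = 3.0, CD13 = 2.2, CD38 = 1.2,
         "HLA-DR" = 3.2),
    .pop("PrMo", 0.012, 1.7, CD45 = 2.6, CD33 = 3.4, CD13 = 2.0, CD38 = 2.8,
         "HLA-DR" = 3.0, CD117 = 1.0),
    .pop("MyMo", 0.020, 2.1, CD45 = 2.4, CD13 = 2.4, CD33 = 2.8, CD38 = 2.2),
    .pop("MonoBer", 0.008, 1.4, CD45 = 2.0, CD34 = 1.5, CD38 = 3.0,
         CD117 = 1.8, CD33 = 2.8, CD13 = 2.0, "HLA-DR" = 2.8),
    .pop("LyT-CD4", 0.110, 1.0, CD45 = 4.0, CD7 = 3.2),
    .pop("LyT-CD8", 0.075, 1.0, CD45 = 4.0, CD7 = 3.8, CD56 = 0.8),
    .pop("LyB", 0.040, 0.95, CD45 = 3.8, CD19 = 3.2, "HLA-DR" = 2.8),
    .pop("NK", 0.030, 1.05, CD45 = 3.8, CD7 = 3.0, CD56 = 3.2),
    .pop("HTG", 0.020, 0.9, CD45 = 2.4, CD19 = 2.8, CD38 = 3.6, CD34 = 0.5,
         "HLA-DR" = 2.6),
    .pop("Ber1", 0.005, 1.15, CD45 = 1.9, CD34 = 3.1, CD38 = 0.35,
         CD117 = 2.8, CD13 = 1.6, CD33 = 1.4, "HLA-DR" = 2.8),
    .pop("Ber2", 0.007, 1.2, CD45 = 2.0, CD34 = 3.0, CD38 = 2.9,
         CD117 = 2.9, CD13 = 1.8, CD33 = 1.8, "HLA-DR" = 3.0),
    # rare immature progenitors sharing the leukemia-like phenotype region;
    # in normal marrow these cells amount to well under 0.2% of leukocytes
    .pop("Ber3", 0.0010, 1.3, sdFluor = 0.35, CD45 = 1.6, CD34 = 3.3,
         CD38 = 1.2, CD117 = 3.1, CD13 = 2.7, CD33 = 1.6, "HLA-DR" = 3.0,
         CD7 = 2.9, CD56 = 1.6),
    .pop("Eo", 0.020, 3.1, CD45 = 2.8, CD13 = 2.4, CD33 = 1.6, CD38 = 1.2),
    .pop("Baso", 0.008, 1.25, CD45 = 2.6, CD38 = 2.6, CD33 = 1.8, CD13 = 1.7),
    .pop("PC", 0.004, 1.1, CD45 = 1.6, CD38 = 4.6, CD19 = 1.2),
    .pop("pDC", 0.004, 1.0, CD45 = 2.7, "HLA-DR" = 3.4, CD38 = 2.6,
         CD33 = 1.2, CD7 = 1.0)),
  "AML-A" = list(
    .pop("Gran", NA, 2.7, CD45 = 2.2, CD13 = 3.0, CD33 = 1.5, CD16 = 3.4,
         CD11b = 3.2, CD64 = 1.0, CD38 = 1.0),
    .pop("IG2", 0.040, 2.5, CD45 = 1.9, CD13 = 2.6, CD33 = 2.6, CD16 = 1.8,
         CD11b = 2.4, CD38 = 1.5),
    .pop("IG1", 0.030, 2.3, CD45 = 1.7, CD13 = 1.8, CD33 = 3.0, CD16 = 0.6,
         CD11b = 1.5, CD38 = 2.0),
    .pop("PrMy", 0.020, 2.2, CD45 = 1.8, CD13 = 2.8, CD33 = 3.0, CD38 = 3.0,
         CD64 = 1.6),
    .pop("Mo", 0.080, 1.9, CD45 = 3.4, CD14 = 3.8, CD16 = 0.8, CD64 = 3.2,
         CD33 = 3.8, CD13 = 2.6, "HLA-DR" = 3.0, CD38 = 2.4, CD11b = 3.0),
    .pop("Mo3", 0.008, 1.8, CD45 = 3.6, CD14 = 1.4, CD16 = 2.8, CD64 = 1.8,
         CD33 = 3.0, "HLA-DR" = 3.2, CD38 = 1.2, CD11b = 2.8),
    .pop("PrMo", 0.012, 1.7, CD45 = 2.6, CD14 = 2.0, CD64 = 3.0, CD33 = 3.4,
         "HLA-DR" = 3.0, CD38 = 2.8),
    .pop("Ly", 0.284, 1.0, CD45 = 4.0),
    .pop("HTG", 0.020, 0.95, CD45 = 2.4, CD38 = 3.6, "HLA-DR" = 2.6),
    .pop("Ber1", 0.005, 1.15, CD45 = 1.9, CD34 = 3.1, CD38 = 0.35,
         CD13 = 1.6, CD33 = 1.4, "HLA-DR" = 2.8),
    .pop("Ber2", 0.007, 1.2, CD45 = 2.0, CD34 = 3.0, CD38 = 2.9, CD13 = 1.8,
         CD33 = 1.8, "HLA-DR" = 3.0),
    .pop("MonoBer", 0.008, 1.4, CD45 = 2.0, CD34 = 1.5, CD38 = 3.0,
         CD33 = 2.8, CD64 = 2.0, "HLA-DR" = 2.8),
    .pop("Ber3", 0.0010, 1.3, sdFluor = 0.35, CD45 = 1.6, CD34 = 3.3,
         CD38 = 1.2, CD13 = 2.7, CD33 = 1.6, "HLA-DR" = 3.0, CD14 = 0.4,
         CD16 = 0.4, CD64 = 1.2, CD11b = 0.6),
    .pop("Eo", 0.020, 3.1, CD45 = 2.8, CD13 = 2.4, CD16 = 1.0),
    .pop("Baso", 0.008, 1.25, CD45 = 2.6, CD38 = 2.6, CD13 = 1.7),
    .pop("PC", 0.004, 1.1, CD45 = 1.6, CD38 = 4.6),
    .pop("pDC", 0.004, 1.0, CD45 = 2.7, "HLA-DR" = 3.4, CD38 = 2.6,
         CD64 = 1.0)),
  "ALL-A" = list(
    .pop("Gran", NA, 2.7, CD45 = 2.2, CD66c = 2.6),
    .pop("Mo", 0.090, 1.9, CD45 = 3.4, CD123 = 1.2),
    .pop("LyT", 0.200, 1.0, CD45 = 4.0),
    .pop("NK", 0.030, 1.05, CD45 = 3.8),
    .pop("LyB", 0.040, 0.95, CD45 = 3.8, CD19 = 3.2, CD20 = 3.0, CD22 = 2.8),
    .pop("HTG1", 0.010, 0.9, CD45 = 2.0, CD19 = 2.8, CD10 = 3.2, CD34 = 1.8,
         CD38 = 3.4, CD58 = 3.0),
    .pop("HTG2", 0.015, 0.9, CD45 = 2.8, CD19 = 3.0, CD10 = 2.6, CD38 = 3.0,
         CD20 = 1.5, CD58 = 2.4),
    .pop("Ber", 0.012, 1.15, CD45 = 1.9, CD34 = 3.0, CD38 = 2.2),
    .pop("Eo", 0.020, 3.1, CD45 = 2.8, CD66c = 1.5),
    .pop("Baso", 0.008, 1.25, CD45 = 2.6, CD123 = 2.8),
    .pop("PC", 0.004, 1.1, CD45 = 1.6, CD38 = 4.6, CD19 = 1.2),
    .pop("pDC", 0.004, 1.0, CD45 = 2.7, CD123 = 3.4)),
  "ALL-B" = list(
    .pop("Gran", NA, 2.7, CD45 = 2.2),
    .pop("Mo", 0.090, 1.9, CD45 = 3.4),
    .pop("LyT", 0.180, 1.0, CD45 = 4.0, CD3 = 3.4, CD5 = 3.2, CD7 = 3.2,
         CD2 = 3.0),
    .pop("NK", 0.030, 1.05, CD45 = 3.8, CD7 = 3.0, CD56 = 3.2, CD2 = 2.4),
    .pop("LyB", 0.040, 0.95, CD45 = 3.8, CD19 = 3.2),
    .pop("HTG", 0.020, 0.9, CD45 = 2.4, CD19 = 2.8, CD10 = 3.0, CD38 = 3.4,
         CD34 = 0.5),
    .pop("Ber", 0.012, 1.15, CD45 = 1.9, CD34 = 3.0, CD38 = 2.2),
    .pop("Eo", 0.020, 3.1, CD45 = 2.8),
    .pop("Baso", 0.008, 1.25, CD45 = 2.6, CD38 = 2.6),
    .pop("PC", 0.004, 1.1, CD45 = 1.6, CD38 = 4.6)))

#' Synthetic normal-marrow population table for a panel
#'
#' One row per population: \code{population}, \code{frequency}, and
#' per-clustering-marker \code{mean.}/\code{sd.} columns on the transformed
#' (arcsinh) scale. Frequencies sum to 1; the dominant granulocyte
#' population absorbs the remainder. All values are synthetic fixtures.
#'
#' @inheritParams bmPanel
#' @return a data.frame population spec (see \code{\link{simulateSample}}).
#' @export
bmPopulationSpecs <- function(name = c("AML-B", "AML-A", "ALL-A", "ALL-B")) {
  name <- match.arg(name)
  .popsToSpec(.fillDominant(.POPS[[name]]), .PANEL_MARKERS[[name]])
}

#' Synthetic AML blast phenotype for spike-in experiments
#'
#' A tight aberrant progenitor population (CD34+ CD117+ HLA-DR+ with
#' lineage-infidelity markers where the panel carries them), positioned in a
#' region of marrow space that normal samples occupy only marginally - the
#' measurable-residual-disease scenario.
#'
#' @inheritParams bmPanel
#' @return a single-row population spec data.frame (frequency 1).
#' @export
amlBlastSpec <- function(name = c("AML-B", "AML-A")) {
  name <- match.arg(name)
  p <- switch(name,
    "AML-B" = .pop("blast", 1, 1.3, sdFluor = 0.25, CD45 = 1.6, CD34 = 3.3,
                   CD38 = 1.2, CD117 = 3.1, CD13 = 2.7, CD33 = 1.6,
                   "HLA-DR" = 3.0, CD7 = 2.9, CD56 = 1.6),
    "AML-A" = .pop("blast", 1, 1.3, sdFluor = 0.25, CD45 = 1.6, CD34 = 3.3,
                   CD38 = 1.2, CD13 = 2.7, CD33 = 1.6, "HLA-DR" = 3.0,
                   CD14 = 0.4, CD16 = 0.4, CD64 = 1.2, CD11b = 0.6))
  .popsToSpec(list(p), .PANEL_MARKERS[[name]])
}
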