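#' @include AllClasses.R
NULL

## Draw population events in transformed space, inverse-transform to the
## raw measurement scale, and apply the panel's spillover so that the
## standard compensate -> transform pipeline recovers the intended
## phenotypes. Side scatter is truncated at a small positive transformed
## value so raw SSC stays non-negative.

.specMarkers <- function(spec) {
  sub("^mean\\.", "", grep("^mean\\.", names(spec), value = TRUE))
}

.drawPopulationBlock <- function(spec, rowIdx, n, markers) {
  out <- matrix(0, n, length(markers), dimnames = list(NULL, markers))
  for (m in markers) {
    mu <- spec[[paste0("mean.", m)]][rowIdx]
    sdv <- spec[[paste0("sd.", m)]][rowIdx]
    out[, m] <- stats::rnorm(n, mu, sdv)
  }
  out[, "SSC"] <- pmax(out[, "SSC"], 0.01)
  out
}

.transformedToRaw <- function(tmat, panel) {
  ch <- panel@channels
  fluorCh <- ch$channel[ch$role == "fluorescence"]
  fluorMk <- ch$marker[ch$role == "fluorescence"]
  cof <- ch$cofactor[match(fluorCh, ch$channel)]
  sscCof <- ch$cofactor[ch$role == "side_scatter"][1]
  rawF <- sweep(sinh(tmat[, fluorMk, drop = FALSE]), 2, cof, "*")
  if (length(panel@spillover))
    rawF <- rawF %*% panel@spillover  # observed = true %*% spillover
  rawSSC <- sinh(tmat[, "SSC"]) * sscCof
  n <- nrow(tmat)
  fsc <- pmax(stats::rnorm(n, 45000 + 20000 * (tmat[, "SSC"] - 1), 8000), 1)
  out <- cbind(fsc, rawSSC, rawF, seq_len(n) * 0.1)
  colnames(out) <- c("FSC", "SSC", fluorCh, "TIME")
  out[, ch$channel, drop = FALSE]
}

#' Simulate one bone-marrow sample
#'
#' Per-population event counts are drawn multinomially from the spec
#' frequencies; events are Gaussian in transformed (arcsinh) space and
#' inverse-transformed to the raw measurement scale, with the panel's
#' spillover applied forward. Events are shuffled; the population of origin
#' is kept as a ground-truth label (never as a channel).
#'
#' @param spec population spec data.frame (see
#'   \code{\link{bmPopulationSpecs}}): columns \code{population},
#'   \code{frequency}, \code{mean.<marker>}, \code{sd.<marker>} (including
#'   \code{SSC}); frequencies must sum to 1.
#' @param panel the matching \linkS4class{PanelDefinition}.
#' @param nEvents number of events.
#' @param seed RNG seed.
#' @param sampleId sample label.
#' @return a raw \linkS4class{EventMatrix} with truth labels.
#' @export
simulateSample <- function(spec, panel, nEvents = 10000L, seed = 1L,
                           sampleId = "sim1") {
  freq <- spec$frequency
  if (abs(sum(freq) - 1) > 1e-9)
    stop("validation error: population frequencies must sum to 1 (got ",
         format(sum(freq)), ")")
  markers <- .specMarkers(spec)
  withSeed(seed, {
    counts <- as.vector(stats::rmultinom(1, nEvents, freq))
    blocks <- vector("list", nrow(spec))
    for (i in seq_len(nrow(spec)))
      blocks[[i]] <- .drawPopulationBlock(spec, i, counts[i], markers)
    tmat <- do.call(rbind, blocks)
    truth <- rep(spec$population, counts)
    perm <- sample.int(nEvents)
    raw <- .transformedToRaw(tmat[perm, , drop = FALSE], panel)
    eventMatrix(raw, markerNames = panel@channels$marker,
                sampleIds = sampleId, state = "raw", truth = truth[perm])
  })
}

#' Simulate a cohort of normal marrow samples
#'
#' Per-sample population frequencies are drawn from a Dirichlet with
#' parameters \code{concentration * base frequencies}, emulating
#' inter-donor variation; each sample then gets an independent seed derived
#' from the master seed. Defaults emulate a 19-donor normal cohort of
#' 10,000 events per sample.
#'
#' @param panel a \linkS4class{PanelDefinition} from \code{\link{bmPanel}}.
#' @param nSamples number of donors.
#' @param nEvents events per sample.
#' @param concentration Dirichlet concentration (> 0); larger = less
#'   inter-donor variation. The default 5000 yields occupancy variability
#'   typical of a harmonized acquisition protocol: frequency CV about 1.5
#'   percent for granulocytes, 4-7 percent for lymphocyte subsets and
#'   15-35 percent for the rarest subsets.
#' @param seed master seed.
#' @param spec base population spec (default
#'   \code{bmPopulationSpecs(panel name)}).
#' @return list of raw \linkS4class{EventMatrix} objects with sample ids
#'   \code{"normal01"}, \code{"normal02"}, ...
#' @export
simulateCohort <- function(panel, nSamples = 19L, nEvents = 10000L,
                           concentration = 5000, seed = 1L, spec = NULL) {
  stopifnot(nSamples >= 1L, concentration > 0)
  if (is.null(spec)) spec <- bmPopulationSpecs(panel@name)
  seeds <- deriveSeeds(seed, nSamples + 1L)
  freqs <- withSeed(seeds[1], {
    alpha <- concentration * spec$frequency
    g <- matrix(stats::rgamma(nSamples * length(alpha), shape = alpha),
                nrow = nSamples, byrow = TRUE)
    g / rowSums(g)
  })
  lapply(seq_len(nSamples), function(i) {
    s <- spec
    s$frequency <- freqs[i, ]
    simulateSample(s, panel, nEvents = nEvents, seed = seeds[i + 1L],
                   sampleId = sprintf("normal%02d", i))
  })
}

#' Spike an abnormal (blast) population into a sample
#'
#' Replaces a random fraction of events with draws from the blast spec, so
#' the realized blast share is \code{round(fraction * n) / n}. Truth labels
#' are updated.
#'
#' @param events a raw \linkS4class{EventMatrix} (e.g. a simulated normal).
#' @param blastSpec single-row population spec (see
#'   \code{\link{amlBlastSpec}}).
#' @param panel the \linkS4class{PanelDefinition}.
#' @param fraction fraction of events to replace, between 0 and 1.
#' @param seed RNG seed.
#' @return the spiked \linkS4class{EventMatrix}.
#' @export
spikeAbnormal <- function(events, blastSpec, panel, fraction, seed = 1L) {
  if (!is.numeric(fraction) || fraction < 0 || fraction > 1)
    stop("validation error: fraction must be in [0, 1]")
  n <- nEvents(events)
  k <- round(fraction * n)
  if (k == 0L) return(events)
  markers <- .specMarkers(blastSpec)
  withSeed(seed, {
    rows <- sample.int(n, k)
    tmat <- .drawPopulationBlock(blastSpec, 1L, k, markers)
    raw <- .transformedToRaw(tmat, panel)
    v <- events@exprs
    v[rows, ] <- raw[, colnames(v), drop = FALSE]
    truth <- events@truth
    if (length(truth)) truth[rows] <- blastSpec$population[1]
    methods::initialize(events, exprs = v, truth = truth)
  })
}
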