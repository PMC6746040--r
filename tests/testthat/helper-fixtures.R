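## Small fixtures shared across test files. Everything is generated in code.

# minimal 3-fluorescence panel without spillover, for unit tests
tinyPanel <- function(spill = NULL) {
  panelDefinition("tiny", data.frame(
    channel = c("FSC", "SSC", "FL1", "FL2", "FL3", "TIME"),
    marker = c("", "SSC", "CD45", "CD34", "CD38", ""),
    role = c("forward_scatter", "side_scatter", "fluorescence",
             "fluorescence", "fluorescence", "time"),
    stringsAsFactors = FALSE), spill)
}

randomEvents <- function(n = 50, channels = c("A", "B", "C"), seed = 1,
                         state = "raw") {
  set.seed(seed)
  eventMatrix(matrix(abs(rnorm(n * length(channels), 100, 30)),
                     n, length(channels), dimnames = list(NULL, channels)),
              state = state)
}

# compact marrow-like spec used where the full 22-population default would
# be slow: 4 major populations plus the three CD34/CD38 progenitor subsets
# at slightly elevated frequency so they resolve at small event counts
compactSpec <- function(panel) {
  base <- bmPopulationSpecs(panel@name)
  keep <- c("Gran", "Mo", "LyT-CD4", "LyB", "Ber1", "Ber2", "MonoBer")
  spec <- base[base$population %in% keep, ]
  spec$frequency <- c(0.50, 0.10, 0.20, 0.11, 0.03, 0.03, 0.03)
  spec
}

## one reduced-scale reference template per session, reused across files
.fixtureEnv <- new.env(parent = emptyenv())

sharedCohort <- function() {
  if (is.null(.fixtureEnv$cohort)) {
    panel <- bmPanel("AML-B")
    .fixtureEnv$cohort <- simulateCohort(panel, nSamples = 6,
                                         nEvents = 2000, seed = 11)
  }
  .fixtureEnv$cohort
}

sharedTemplate <- function() {
  if (is.null(.fixtureEnv$template)) {
    panel <- bmPanel("AML-B")
    .fixtureEnv$template <- buildReference(sharedCohort(), panel,
                                           referenceConfig(), seed = 11)
  }
  .fixtureEnv$template
}
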