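test_that("mapped occupancy is conserved and the template stays frozen", {
  tpl <- sharedTemplate()
  before <- serialize(tpl, NULL)
  s <- simulateCohort(bmPanel("AML-B"), nSamples = 1, nEvents = 1500,
                      seed = 401)[[1]]
  m <- mapSample(tpl, s)
  expect_equal(sum(occupancy(m)), 1, tolerance = 1e-9)
  expect_identical(length(m@assignments), nEvents(s))
  ranges <- computeNormalRanges(tpl)
  invisible(compareToReference(m, tpl, ranges))
  expect_identical(serialize(tpl, NULL), before)
})

test_that("a sample missing a panel channel fails naming the channel", {
  tpl <- sharedTemplate()
  s <- sharedCohort()[[1]]
  idx <- which(markerNames(s) == "CD117")
  crippled <- eventMatrix(exprs(s)[, -idx],
                          markerNames = markerNames(s)[-idx],
                          sampleIds = sampleIds(s))
  expect_error(mapSample(tpl, crippled), "CD117")
})

test_that("z-scores, fold-changes and flags obey the thresholds", {
  occ <- matrix(c(0.60, 0.39, 0.01,
                  0.62, 0.37, 0.01,
                  0.61, 0.38, 0.01), 3, 3, byrow = TRUE,
                dimnames = list(paste0("s", 1:3), NULL))
  cb <- matrix(rnorm(6), 3, 2, dimnames = list(NULL, c("a", "b")))
  model <- new("SOMModel", gridRows = 1L, gridCols = 3L, codebook = cb,
               scaling = new("ScalingStats", channels = c("a", "b"),
                             location = c(0, 0), spread = c(1, 1)),
               meta = list(seed = 1))
  tree <- buildMST(model); tree@layout <- layoutMST(tree, 1)
  tpl <- new("ReferenceTemplate",
             panel = panelDefinition("t", data.frame(
               channel = c("a", "b"), marker = c("a", "b"),
               role = c("fluorescence", "side_scatter"),
               stringsAsFactors = FALSE)),
             model = model, tree = tree,
             nodeStats = data.frame(node = 1:3, count = c(61, 38, 1) * 10L,
                                    pct = c(61, 38, 1)),
             occupancy = occ,
             markerBreaks = matrix(0, 2, 3, dimnames = list(
               c("a", "b"), c("q20", "q50", "q80"))),
             nodeLabels = list("gran", "lymph", "rare"),
             provenance = list(sampleIds = paste0("s", 1:3), seed = 1L,
                               nEvents = 3000L, version = "0"))
  ranges <- computeNormalRanges(tpl, sdFloor = 0.005, moderate = FALSE)
  mapped <- new("MappedSample", sampleId = "p", assignments = integer(0),
                occupancy = c(0.05, 0.85, 0.10), eventCount = 0L)
  mapped@assignments <- rep(1:3, round(1000 * mapped@occupancy))
  mapped@eventCount <- 1000L
  rep <- compareToReference(mapped, tpl, ranges,
                            compareThresholds(zHi = 3, minFold = 2))
  tab <- rep@nodeTable
  expect_equal(tab$z, (mapped@occupancy - ranges@mean) / ranges@sd,
               tolerance = 1e-12)
  expect_equal(tab$log2fc,
               log2((mapped@occupancy + 1e-3) / (ranges@mean + 1e-3)),
               tolerance = 1e-12)
  # node 1 collapsed -> deficit; nodes 2 and 3 exploded -> excess
  expect_identical(tab$flag, c("deficit", "excess", "excess"))
  expect_equal(rep@summary$excessBurden, 95)
  expect_identical(rep@summary$deficitLabels, "gran")
  expect_error(compareToReference(mapped, tpl,
                                  new("NormalRanges", mean = 0.5, sd = 0.1,
                                      min = 0.4, max = 0.6, sdFloor = 0.1)),
               "node count")
})

test_that("blast spike-ins are recovered and respond monotonically", {
  tpl <- sharedTemplate()
  ranges <- computeNormalRanges(tpl)
  panel <- bmPanel("AML-B")
  blast <- amlBlastSpec("AML-B")
  fresh <- simulateCohort(panel, nSamples = 1, nEvents = 2000,
                          seed = 402)[[1]]
  recovered <- sapply(c(0.0144, 0.05, 0.137), function(f) {
    sp <- spikeAbnormal(fresh, blast, panel, f, seed = 403)
    compareToReference(mapSample(tpl, sp), tpl, ranges)@summary$excessBurden
  })
  expect_false(is.unsorted(recovered))
  expect_gt(recovered[3], 10)
  expect_lt(recovered[3], 18)
  expect_gt(recovered[1], 0.5)
})

test_that("removing granulocytic maturation flags labeled deficits", {
  tpl <- sharedTemplate()
  labels <- labelNodes(tpl, phenotypeRules(
    list(label = "granulocytic", clauses = c(CD13 = "pos", CD45 = "lo"))))
  nodeLabels(tpl) <- labels
  ranges <- computeNormalRanges(tpl)
  panel <- bmPanel("AML-B")
  spec <- bmPopulationSpecs("AML-B")
  drop <- spec$population %in% c("Gran", "IG1", "IG2", "PrMy")
  spec$frequency[drop] <- 0
  spec$frequency <- spec$frequency / sum(spec$frequency)
  s <- simulateSample(spec, panel, 2000, seed = 404)
  rep <- compareToReference(mapSample(tpl, s), tpl, ranges)
  expect_gt(length(rep@summary$deficitNodes), 5)
  expect_true("granulocytic" %in% rep@summary$deficitLabels)
})

test_that("the backgating table exposes raw channels per event", {
  tpl <- sharedTemplate()
  s <- sharedCohort()[[3]]
  m <- mapSample(tpl, s)
  bt <- backgateTable(m, s, tpl, "CD45", "SSC")
  expect_identical(nrow(bt), nEvents(s))
  expect_identical(names(bt)[1:2], c("CD45", "SSC"))
  cd45col <- which(markerNames(s) == "CD45")
  expect_identical(bt$CD45, unname(exprs(s)[, cd45col]))
  expect_identical(bt$SSC, unname(exprs(s)[, "SSC"]))
  expect_true(all(bt$node %in% seq_len(100)))
  expect_error(backgateTable(m, s, tpl, "CD999", "SSC"), "CD999")
})
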