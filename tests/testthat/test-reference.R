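tinyTemplate <- function(occ, nEventsTotal = 1000L) {
  # minimal 2-node template wrapping a given occupancy matrix
  cb <- matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE,
               dimnames = list(NULL, c("a", "b")))
  model <- new("SOMModel", gridRows = 1L, gridCols = 2L, codebook = cb,
               scaling = new("ScalingStats", channels = c("a", "b"),
                             location = c(0, 0), spread = c(1, 1)),
               meta = list(seed = 1))
  tree <- buildMST(model)
  tree@layout <- layoutMST(tree, seed = 1)
  new("ReferenceTemplate",
      panel = panelDefinition("t", data.frame(
        channel = c("a", "b"), marker = c("a", "b"),
        role = c("fluorescence", "side_scatter"),
        stringsAsFactors = FALSE)),
      model = model, tree = tree,
      nodeStats = data.frame(node = 1:2, count = c(500L, 500L),
                             pct = c(50, 50)),
      occupancy = occ,
      markerBreaks = matrix(0, 2, 3,
                            dimnames = list(c("a", "b"),
                                            c("q20", "q50", "q80"))),
      nodeLabels = list(character(0), character(0)),
      provenance = list(sampleIds = rownames(occ), seed = 1L,
                        nEvents = nEventsTotal, version = "0"))
}

test_that("the shared reference build has the expected structure", {
  tpl <- sharedTemplate()
  expect_identical(nNodes(tpl), 100L)
  expect_identical(nrow(tpl@tree@edges), 99L)
  expect_identical(ncol(codebook(tpl)), 11L)
  occ <- occupancy(tpl)
  expect_identical(nrow(occ), 6L)
  expect_true(all(abs(rowSums(occ) - 1) < 1e-9))
  expect_identical(sum(nodeStats(tpl)$count),
                   tpl@provenance$nEvents)
  expect_equal(sum(nodeStats(tpl)$pct), 100, tolerance = 1e-6)
  expect_identical(nrow(tpl@tree@layout), 100L)
})

test_that("mapping a constituent normal reproduces its stored row exactly", {
  tpl <- sharedTemplate()
  cohort <- sharedCohort()
  for (i in c(1L, 4L)) {
    m <- mapSample(tpl, cohort[[i]])
    expect_identical(occupancy(m), unname(occupancy(tpl)[i, ]))
  }
})

test_that("rebuilding with the same seed is byte-identical", {
  panel <- bmPanel("AML-B")
  cohort <- simulateCohort(panel, nSamples = 3, nEvents = 600, seed = 21)
  cfg <- referenceConfig(gridRows = 4, gridCols = 4, epochs = 4,
                         refineEpochs = 2)
  t1 <- suppressWarnings(buildReference(cohort, panel, cfg, seed = 5))
  t2 <- suppressWarnings(buildReference(cohort, panel, cfg, seed = 5))
  expect_identical(codebook(t1), codebook(t2))
  expect_identical(occupancy(t1), occupancy(t2))
  d1 <- tempfile(); d2 <- tempfile()
  saveTemplate(t1, d1); saveTemplate(t2, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
  t3 <- suppressWarnings(buildReference(cohort, panel, cfg, seed = 6))
  expect_false(identical(codebook(t1), codebook(t3)))
})

test_that("a saved template reloads to an equivalent object", {
  tpl <- sharedTemplate()
  d <- tempfile()
  saveTemplate(tpl, d)
  back <- loadTemplate(d)
  expect_identical(codebook(back), codebook(tpl))
  expect_identical(back@model@scaling@location, tpl@model@scaling@location)
  expect_identical(occupancy(back), occupancy(tpl))
  expect_identical(back@tree@edges$weight, tpl@tree@edges$weight)
  expect_identical(unname(back@tree@layout), unname(tpl@tree@layout))
  # a sample maps identically through the reloaded template
  s <- sharedCohort()[[2]]
  expect_identical(occupancy(mapSample(back, s)),
                   occupancy(mapSample(tpl, s)))
})

test_that("node statistics handle empty nodes and report known medians", {
  panel <- tinyPanel()
  v <- matrix(1, 10, 6, dimnames = list(NULL, panel@channels$channel))
  v[, "FL1"] <- c(rep(7, 6), rep(2, 4))
  events <- eventMatrix(v, state = "transformed")
  cb <- matrix(0, 4, 4, dimnames = list(NULL, c("SSC", "FL1", "FL2", "FL3")))
  model <- new("SOMModel", gridRows = 2L, gridCols = 2L, codebook = cb,
               scaling = new("ScalingStats",
                             channels = c("SSC", "FL1", "FL2", "FL3"),
                             location = rep(0, 4), spread = rep(1, 4)),
               meta = list(seed = 1))
  assignments <- c(rep(1L, 6), rep(3L, 4))
  ns <- computeNodeStats(events, assignments, model, panel)
  expect_identical(ns$count, c(6L, 0L, 4L, 0L))
  expect_equal(sum(ns$count), 10L)
  expect_equal(ns$pct, c(60, 0, 40, 0))
  expect_identical(ns$med_FL1[1], 7)   # all events equal 7 on FL1
  expect_identical(ns$med_FL1[3], 2)
  expect_true(all(is.na(ns$med_FL1[c(2, 4)])))   # empty nodes undefined
  # back-transform returns the measurement scale
  expect_equal(ns$medRaw_FL1[1], sinh(7) * 150, tolerance = 1e-9)
})

test_that("a designated node set holding 18 of 10000 events reports 0.18%", {
  panel <- tinyPanel()
  v <- matrix(0, 10000, 6, dimnames = list(NULL, panel@channels$channel))
  events <- eventMatrix(v, state = "transformed")
  assignments <- rep(1L, 10000)
  assignments[1:11] <- 3L
  assignments[12:18] <- 4L
  cb <- matrix(0, 4, 4, dimnames = list(NULL, c("SSC", "FL1", "FL2", "FL3")))
  model <- new("SOMModel", gridRows = 2L, gridCols = 2L, codebook = cb,
               scaling = new("ScalingStats",
                             channels = c("SSC", "FL1", "FL2", "FL3"),
                             location = rep(0, 4), spread = rep(1, 4)),
               meta = list(seed = 1))
  ns <- computeNodeStats(events, assignments, model, panel)
  expect_equal(sum(ns$pct[c(3, 4)]), 0.18, tolerance = 1e-12)
})

test_that("normal ranges match hand arithmetic on a 3x2 matrix", {
  occ <- matrix(c(0.6, 0.4,
                  0.5, 0.5,
                  0.7, 0.3), 3, 2, byrow = TRUE,
                dimnames = list(paste0("s", 1:3), NULL))
  tpl <- tinyTemplate(occ)
  r <- computeNormalRanges(tpl, sdFloor = 1e-4, moderate = FALSE)
  expect_equal(r@mean, c(0.6, 0.4))
  expect_equal(r@sd, rep(0.1, 2), tolerance = 1e-12)   # sd of .5,.6,.7
  expect_equal(r@min, c(0.5, 0.3))
  expect_equal(r@max, c(0.7, 0.5))
})

test_that("degenerate occupancy matrices floor the sd", {
  same <- matrix(0.5, 4, 2, dimnames = list(paste0("s", 1:4), NULL))
  r <- computeNormalRanges(tinyTemplate(same), sdFloor = 1e-3)
  expect_equal(r@sd, rep(1e-3, 2))
  one <- matrix(c(0.5, 0.5), 1, 2, dimnames = list("s1", NULL))
  expect_warning(r1 <- computeNormalRanges(tinyTemplate(one), sdFloor = 1e-3),
                 "single")
  expect_equal(r1@sd, rep(1e-3, 2))
  expect_error(computeNormalRanges(
    tinyTemplate(matrix(numeric(0), 0, 2))), "input error")
})

test_that("variance moderation pulls outlier sds toward the trend", {
  set.seed(9)
  occ <- matrix(abs(rnorm(19 * 20, 0.05, 0.005)), 19, 20)
  occ <- occ / rowSums(occ)
  occ <- cbind(occ * 0.9, matrix(0.1 / 30, 19, 30) +
                 matrix(rnorm(19 * 30, 0, 2e-4), 19, 30))
  occ <- pmax(occ, 0)
  occ <- occ / rowSums(occ)
  cb <- matrix(rnorm(100), 50, 2, dimnames = list(NULL, c("a", "b")))
  model <- new("SOMModel", gridRows = 5L, gridCols = 10L, codebook = cb,
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
             nodeStats = data.frame(node = 1:50, count = rep(20L, 50),
                                    pct = rep(2, 50)),
             occupancy = occ, markerBreaks = matrix(0, 2, 3,
               dimnames = list(c("a", "b"), c("q20", "q50", "q80"))),
             nodeLabels = rep(list(character(0)), 50),
             provenance = list(sampleIds = paste0("s", 1:19), seed = 1L,
                               nEvents = 190000L, version = "0"))
  raw <- computeNormalRanges(tpl, moderate = FALSE)
  mod <- computeNormalRanges(tpl, moderate = TRUE)
  expect_identical(raw@mean, mod@mean)
  # moderation shrinks the spread of sd estimates around the trend
  grp <- rep(1:2, c(20, 30))
  rawCV <- tapply(raw@sd, grp, function(s) sd(s) / mean(s))
  modCV <- tapply(mod@sd, grp, function(s) sd(s) / mean(s))
  expect_true(all(modCV <= rawCV + 1e-9))
})
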