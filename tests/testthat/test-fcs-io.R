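test_that("FCS write/read round-trips values and names", {
  x <- randomEvents(37, c("FSC", "SSC", "FL1"), seed = 2)
  x@markerNames <- c("", "SSC", "CD45")
  f <- tempfile(fileext = ".fcs")
  writeFCS(x, f)
  back <- readFCS(f)
  expect_identical(channelNames(back$events), c("FSC", "SSC", "FL1"))
  expect_identical(markerNames(back$events), c("", "SSC", "CD45"))
  # float32 rounding only
  expect_lt(max(abs(exprs(back$events) - exprs(x)) / pmax(abs(exprs(x)), 1)),
            1e-6)
  expect_identical(eventState(back$events), "raw")
  expect_identical(back$meta$keywords[["$TOT"]], "37")
  expect_identical(back$meta$keywords[["$PAR"]], "3")
})

test_that("round-trip holds for randomized matrices", {
  for (seed in 1:5) {
    n <- sample(1:200, 1)
    k <- sample(1:8, 1)
    x <- randomEvents(n, paste0("P", seq_len(k)), seed = seed)
    f <- tempfile(fileext = ".fcs")
    writeFCS(x, f)
    back <- readFCS(f)$events
    expect_equal(exprs(back), exprs(x), tolerance = 1e-6)
    expect_identical(channelNames(back), channelNames(x))
  }
})

# a file assembled byte by byte from the FCS 3.1 layout, independent of
# the package's writer
buildRawFCS <- function(version = "FCS3.1", datatype = "F",
                        payload = c(1, 2, 3, 4)) {
  d <- "/"
  kw <- c("$BYTEORD", "1,2,3,4", "$DATATYPE", datatype, "$MODE", "L",
          "$TOT", "2", "$PAR", "2",
          "$P1B", "32", "$P1N", "chA", "$P2B", "32", "$P2N", "chB")
  txt <- paste0(d, paste0(kw, d, collapse = ""))
  textBeg <- 58
  textEnd <- textBeg + nchar(txt) - 1
  dataBeg <- textEnd + 1
  dataEnd <- dataBeg + 4 * length(payload) - 1
  hdr <- sprintf("%-10s%8d%8d%8d%8d%8d%8d", version, textBeg, textEnd,
                 dataBeg, dataEnd, 0, 0)
  f <- tempfile(fileext = ".fcs")
  con <- file(f, "wb")
  writeBin(charToRaw(hdr), con)
  writeBin(charToRaw(txt), con)
  writeBin(payload, con, size = 4, endian = "little")
  close(con)
  f
}

test_that("hand-assembled FCS 3.1 bytes parse to the expected matrix", {
  f <- buildRawFCS()
  got <- readFCS(f)
  expect_equal(unname(exprs(got$events)),
               matrix(c(1, 3, 2, 4), 2, 2), tolerance = 1e-7)
  expect_identical(channelNames(got$events), c("chA", "chB"))
})

test_that("unsupported dialects and corrupt files are rejected", {
  expect_error(readFCS(buildRawFCS(datatype = "A")),
               class = "marrowSOM_unsupported_dialect")
  expect_error(readFCS(buildRawFCS(version = "FCS2.0")),
               class = "marrowSOM_unsupported_dialect")
  # truncate the data segment of a valid file
  f <- buildRawFCS()
  bytes <- readBin(f, "raw", file.info(f)$size)
  writeBin(bytes[1:(length(bytes) - 9)], f)
  expect_error(readFCS(f), class = "marrowSOM_corrupt_file")
})

test_that("zero-event and invalid matrices are handled", {
  empty <- eventMatrix(matrix(numeric(0), 0, 2,
                              dimnames = list(NULL, c("a", "b"))),
                       sampleIds = character(0))
  f <- tempfile(fileext = ".fcs")
  writeFCS(empty, f)
  back <- readFCS(f)
  expect_identical(nEvents(back$events), 0L)
  expect_identical(channelNames(back$events), c("a", "b"))

  bad <- randomEvents(5, c("a", "b"))
  bad@exprs[2, 1] <- NaN
  expect_error(writeFCS(bad, tempfile()), "validation|finite")
})

test_that("CSV event tables round-trip with markers, origin and truth", {
  x <- randomEvents(20, c("FL1", "FL2"), seed = 3)
  x@markerNames <- c("CD45", "CD34")
  x@truth <- rep(c("Gran", "LyB"), 10)
  f <- tempfile(fileext = ".csv")
  writeEventsCSV(x, f)
  back <- readEventsCSV(f)
  expect_equal(exprs(back), exprs(x), tolerance = 1e-12)
  expect_identical(markerNames(back), c("CD45", "CD34"))
  expect_identical(truthLabels(back), x@truth)
  expect_identical(sampleIds(back), sampleIds(x))
})

test_that("mergeEvents concatenates in order and reorders columns", {
  panel <- tinyPanel()
  mk <- panel@channels$marker
  a <- randomEvents(100, panel@channels$channel, seed = 4)
  a@markerNames <- mk
  a@sampleIds <- rep("d1", 100)
  b <- randomEvents(200, panel@channels$channel, seed = 5)
  b@markerNames <- mk
  b@sampleIds <- rep("d2", 200)
  m <- mergeEvents(list(a, b), panel)
  expect_identical(nEvents(m), 300L)
  expect_identical(unique(sampleIds(m)), c("d1", "d2"))
  expect_identical(exprs(m)[1:100, ], exprs(a))

  # permuting a sample's columns must not change the merged values
  perm <- c(3, 1, 6, 2, 5, 4)
  b2 <- eventMatrix(exprs(b)[, perm], markerNames = mk[perm],
                    sampleIds = "d2")
  m2 <- mergeEvents(list(a, b2), panel)
  expect_equal(exprs(m2), exprs(m))
})

test_that("mergeEvents names the sample and channel on mismatch", {
  panel <- tinyPanel()
  a <- randomEvents(10, panel@channels$channel, seed = 6)
  a@markerNames <- panel@channels$marker
  noCD38 <- a
  noCD38@exprs <- a@exprs[, -5]
  noCD38@markerNames <- a@markerNames[-5]
  noCD38@sampleIds <- rep("donorX", 10)
  err <- tryCatch(mergeEvents(list(a, noCD38), panel), error = identity)
  expect_s3_class(err, "marrowSOM_channel_mismatch")
  expect_match(conditionMessage(err), "donorX")
  expect_match(conditionMessage(err), "CD38")
})

test_that("mergeEvents is associative on the value matrix", {
  panel <- tinyPanel()
  ss <- lapply(1:3, function(i) {
    x <- randomEvents(30 + i, panel@channels$channel, seed = i)
    x@markerNames <- panel@channels$marker
    x@sampleIds <- rep(paste0("d", i), nEvents(x))
    x
  })
  all3 <- mergeEvents(ss, panel)
  ab <- mergeEvents(ss[1:2], panel)
  abc <- mergeEvents(list(ab, ss[[3]]), panel)
  expect_equal(exprs(abc), exprs(all3))
})

test_that("filterEvents keeps only selected rows", {
  x <- randomEvents(10, c("a", "b"))
  keep <- rep(c(TRUE, FALSE), 5)
  expect_identical(nEvents(filterEvents(x, keep)), 5L)
  expect_identical(nEvents(filterEvents(x, function(e) exprs(e)[, 1] > -Inf)),
                   10L)
})
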