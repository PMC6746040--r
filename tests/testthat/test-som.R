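scaledMatrix <- function(n, k = 3, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n * k), n, k, dimnames = list(NULL, paste0("c", seq_len(k))))
}

test_that("a 1x1 grid collapses to the data mean", {
  x <- scaledMatrix(200, 4, seed = 1)
  m <- trainSOM(x, gridRows = 1, gridCols = 1, epochs = 3, seed = 1)
  expect_equal(unname(codebook(m))[1, ], unname(colMeans(x)),
               tolerance = 1e-9)
})

test_that("a 2x2 grid recovers four well-separated clouds", {
  set.seed(2)
  centers <- rbind(c(0, 0), c(10, 0), c(0, 10), c(10, 10))
  cloud <- do.call(rbind, lapply(1:4, function(i)
    sweep(matrix(rnorm(400 * 2, 0, 0.3), 400, 2), 2, centers[i, ], "+")))
  truth <- rep(1:4, each = 400)
  m <- trainSOM(cloud, gridRows = 2, gridCols = 2, epochs = 10,
                radiusFinal = 0, seed = 3)
  # oracle: the per-cloud means (what converged k-means would return here)
  oracleMeans <- rowsum(cloud, truth) / 400
  cb <- codebook(m)
  matched <- logical(4)
  for (i in 1:4) {
    d <- sqrt(rowSums(sweep(cb, 2, oracleMeans[i, ], "-")^2))
    j <- which.min(d)
    expect_lt(d[j], 0.1)
    expect_false(matched[j])
    matched[j] <- TRUE
  }
})

test_that("training is bit-identical for identical seed and input", {
  x <- scaledMatrix(300, 5, seed = 4)
  m1 <- trainSOM(x, gridRows = 4, gridCols = 4, epochs = 5, seed = 9)
  m2 <- trainSOM(x, gridRows = 4, gridCols = 4, epochs = 5, seed = 9)
  expect_identical(codebook(m1), codebook(m2))
  m3 <- trainSOM(x, gridRows = 4, gridCols = 4, epochs = 5, seed = 10)
  expect_false(identical(codebook(m1), codebook(m3)))
})

test_that("BMU assignment agrees with brute-force nearest codebook", {
  for (seed in 1:20) {
    set.seed(seed)
    x <- matrix(rnorm(50 * 11), 50, 11)
    cb <- matrix(rnorm(20 * 11), 20, 11)
    model <- new("SOMModel", gridRows = 4L, gridCols = 5L, codebook = cb,
                 scaling = new("ScalingStats", channels = character(0),
                               location = numeric(0), spread = numeric(0)),
                 meta = list(seed = seed))
    got <- assignBMU(x, model)
    oracle <- apply(x, 1, function(ev)
      which.min(apply(cb, 1, function(c) sum((ev - c)^2))))
    expect_identical(got, as.integer(oracle))
  }
})

test_that("BMU ties break toward the lowest node id", {
  cb <- matrix(0, 9, 2)
  cb[3, ] <- c(0, 0)
  cb[9, ] <- c(1, 0)
  cb[-c(3, 9), ] <- 100  # far away
  model <- new("SOMModel", gridRows = 3L, gridCols = 3L, codebook = cb,
               scaling = new("ScalingStats", channels = character(0),
                             location = numeric(0), spread = numeric(0)),
               meta = list(seed = 1))
  expect_identical(assignBMU(matrix(c(0.5, 0), 1, 2), model), 3L)
  # an event exactly on a codebook vector maps to that node
  expect_identical(assignBMU(matrix(c(1, 0), 1, 2), model), 9L)
})

test_that("channel mismatch is a configuration error", {
  x <- scaledMatrix(10, 3)
  m <- trainSOM(x, gridRows = 2, gridCols = 2, epochs = 2, seed = 1)
  colnames(x) <- rev(colnames(x))
  expect_error(assignBMU(x, m), "configuration")
  expect_error(assignBMU(scaledMatrix(10, 4), m), "configuration")
})

test_that("refinement never increases the quantization error", {
  x <- rbind(scaledMatrix(900, 6, seed = 5),
             scaledMatrix(30, 6, seed = 6) + 8)
  base <- trainSOM(x, gridRows = 4, gridCols = 4, epochs = 6,
                   radiusFinal = 0, refineEpochs = 0, seed = 2)
  prev <- quantizationError(x, base)
  for (r in c(2, 5, 10)) {
    m <- trainSOM(x, gridRows = 4, gridCols = 4, epochs = 6,
                  radiusFinal = 0, refineEpochs = r, seed = 2)
    qe <- quantizationError(x, m)
    expect_lte(qe, prev + 1e-12)
    prev <- qe
  }
})

test_that("training warns when nodes outnumber events", {
  expect_warning(trainSOM(scaledMatrix(5, 2), gridRows = 3, gridCols = 3,
                          epochs = 2, seed = 1), "fewer events")
  expect_error(trainSOM(matrix(numeric(0), 0, 2), gridRows = 1,
                        gridCols = 1, seed = 1), "empty")
})

test_that("metaclustering groups codebook blobs deterministically", {
  set.seed(7)
  cbA <- matrix(rnorm(8 * 3, 0, 0.2), 8, 3)
  cbB <- matrix(rnorm(8 * 3, 0, 0.2), 8, 3) + 6
  model <- new("SOMModel", gridRows = 4L, gridCols = 4L,
               codebook = rbind(cbA, cbB),
               scaling = new("ScalingStats", channels = character(0),
                             location = numeric(0), spread = numeric(0)),
               meta = list(seed = 1))
  mc <- metacluster(model, 2)
  expect_identical(length(unique(mc[1:8])), 1L)
  expect_identical(length(unique(mc[9:16])), 1L)
  expect_false(mc[1] == mc[9])
  expect_identical(metacluster(model, 2), mc)
  expect_identical(unname(metacluster(model, 16)), 1:16)
  expect_error(metacluster(model, 0), "input error")
  expect_error(metacluster(model, 17), "input error")
})
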