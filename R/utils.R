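`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `expr` under a fixed RNG state, restoring the caller's stream.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

## Derive child seeds from a master seed, each < 2^31.
deriveSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stopWithClass <- function(class, fmt, ...) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

## Full-precision ("%.17g") CSV writers so serialized templates round-trip
## doubles exactly and rebuilds are byte-identical.
fmtNum <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

writeTableExact <- function(df, path) {
  cols <- lapply(df, function(col) {
    if (is.double(col)) fmtNum(col) else as.character(col)
  })
  lines <- c(paste(names(df), collapse = ","),
             do.call(paste, c(cols, sep = ",")))
  writeLines(lines, path)
}

readTableExact <- function(path) {
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

writeMatrixExact <- function(m, path) {
  df <- as.data.frame(m, check.names = FALSE)
  if (!is.null(rownames(m))) df <- cbind(.row = rownames(m), df)
  writeTableExact(df, path)
}

readMatrixExact <- function(path) {
  df <- readTableExact(path)
  rn <- NULL
  if (".row" %in% names(df)) {
    rn <- as.character(df$.row)
    df$.row <- NULL
  }
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  rownames(m) <- rn
  m
}
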