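#' @include AllClasses.R
NULL

## FCS 3.0/3.1 list-mode reader. Supported dialects: $MODE L, $DATATYPE F
## (float32) or I (16/32-bit integer). ANALYSIS segment and non-essential
## keywords are ignored and not round-tripped.

.fcsHeaderOffsets <- function(hdr) {
  fields <- substring(hdr, seq(11, 51, by = 8), seq(18, 58, by = 8))
  suppressWarnings(as.numeric(trimws(fields)))
}

.parseTextSegment <- function(txt) {
  delim <- substr(txt, 1, 1)
  body <- substring(txt, 2)
  parts <- strsplit(body, delim, fixed = TRUE)[[1]]
  # trailing delimiter leaves a final empty element; drop it
  if (length(parts) %% 2 == 1 && !nzchar(parts[length(parts)]))
    parts <- parts[-length(parts)]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  keys <- toupper(trimws(parts[seq(1, length(parts), by = 2)]))
  vals <- parts[seq(2, length(parts), by = 2)]
  stats::setNames(as.list(vals), keys)
}

#' Read an FCS 3.0/3.1 list-mode file
#'
#' Parses the TEXT and DATA segments of an FCS file. Channel names are taken
#' from \code{$PnN}, marker names from \code{$PnS} where present. Only
#' list-mode files with \code{$DATATYPE} F (float32) or I (16/32-bit
#' integer) are supported; other dialects raise an
#' \code{marrowSOM_unsupported_dialect} error, truncated data segments a
#' \code{marrowSOM_corrupt_file} error.
#'
#' @param path file path.
#' @param sampleId sample-origin label attached to every event (default:
#'   file name without extension).
#' @return list with elements \code{events} (an \linkS4class{EventMatrix},
#'   state \code{"raw"}) and \code{meta} (version, keyword map, byte order,
#'   datatype, and the parsed \code{$SPILLOVER} matrix when present).
#' @export
readFCS <- function(path, sampleId = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sampleId)) sampleId <- sub("\\.[^.]*$", "", basename(path))
  fsize <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- rawToChar(readBin(con, "raw", 58))
  version <- substr(hdr, 1, 6)
  if (!(version %in% c("FCS3.0", "FCS3.1")))
    stopWithClass("marrowSOM_unsupported_dialect",
                  "unsupported FCS version '%s' (FCS 3.0/3.1 only)", version)
  off <- .fcsHeaderOffsets(hdr)
  if (any(is.na(off[1:2])))
    stopWithClass("marrowSOM_corrupt_file", "unreadable header offsets")
  seek(con, off[1])
  txt <- rawToChar(readBin(con, "raw", off[2] - off[1] + 1))
  kw <- .parseTextSegment(txt)

  mode <- toupper(kw[["$MODE"]] %||% "L")
  if (mode != "L")
    stopWithClass("marrowSOM_unsupported_dialect",
                  "unsupported $MODE '%s' (list mode only)", mode)
  dtype <- toupper(kw[["$DATATYPE"]] %||% "")
  if (!(dtype %in% c("F", "I")))
    stopWithClass("marrowSOM_unsupported_dialect",
                  "unsupported $DATATYPE '%s' (F or I only)", dtype)
  byteord <- kw[["$BYTEORD"]] %||% "1,2,3,4"
  endian <- if (byteord %in% c("4,3,2,1")) "big" else "little"
  tot <- as.integer(kw[["$TOT"]] %||% NA)
  par <- as.integer(kw[["$PAR"]] %||% NA)
  if (is.na(tot) || is.na(par))
    stopWithClass("marrowSOM_corrupt_file", "missing $TOT or $PAR")

  chn <- character(par); mrk <- character(par); bits <- integer(par)
  for (i in seq_len(par)) {
    chn[i] <- kw[[sprintf("$P%dN", i)]] %||% sprintf("P%d", i)
    mrk[i] <- kw[[sprintf("$P%dS", i)]] %||% ""
    bits[i] <- as.integer(kw[[sprintf("$P%dB", i)]] %||% "32")
  }
  if (dtype == "F" && any(bits != 32L))
    stopWithClass("marrowSOM_unsupported_dialect",
                  "$DATATYPE F requires 32-bit parameters")
  if (dtype == "I" && !all(bits %in% c(16L, 32L)))
    stopWithClass("marrowSOM_unsupported_dialect",
                  "integer data supported at 16 or 32 bits only")
  if (dtype == "I" && length(unique(bits)) > 1L)
    stopWithClass("marrowSOM_unsupported_dialect",
                  "mixed integer widths not supported")

  dataBeg <- off[3]; dataEnd <- off[4]
  if (is.na(dataBeg) || dataBeg == 0) dataBeg <- as.numeric(kw[["$BEGINDATA"]] %||% 0)
  if (is.na(dataEnd) || dataEnd == 0) dataEnd <- as.numeric(kw[["$ENDDATA"]] %||% 0)

  n <- tot * par
  size <- bits[1] %/% 8L
  if (n > 0) {
    need <- n * size
    if (dataBeg <= 0 || dataBeg + need - 1 > fsize ||
        (dataEnd > 0 && dataEnd - dataBeg + 1 < need))
      stopWithClass("marrowSOM_corrupt_file",
                    "data segment truncated (need %d bytes)", need)
    seek(con, dataBeg)
    vals <- if (dtype == "F")
      readBin(con, "double", n = n, size = 4L, endian = endian)
    else
      readBin(con, "integer", n = n, size = size, endian = endian,
              signed = size > 2L)
    if (length(vals) < n)
      stopWithClass("marrowSOM_corrupt_file", "data segment truncated")
    mat <- matrix(vals, nrow = tot, ncol = par, byrow = TRUE)
  } else {
    mat <- matrix(numeric(0), nrow = 0, ncol = par)
  }
  colnames(mat) <- chn

  spill <- NULL
  if (!is.null(kw[["$SPILLOVER"]])) {
    spill <- tryCatch(.parseSpilloverKeyword(kw[["$SPILLOVER"]]),
                      error = function(e) NULL)
  }
  events <- eventMatrix(mat, markerNames = mrk, sampleIds = sampleId,
                        state = "raw")
  meta <- list(version = version, keywords = kw, byteOrder = endian,
               datatype = if (dtype == "F") "float32" else "int",
               spillover = spill)
  list(events = events, meta = meta)
}

.parseSpilloverKeyword <- function(s) {
  parts <- strsplit(s, ",", fixed = TRUE)[[1]]
  k <- as.integer(parts[1])
  nms <- parts[2:(k + 1)]
  vals <- as.numeric(parts[(k + 2):(k + 1 + k * k)])
  m <- matrix(vals, k, k, byrow = TRUE, dimnames = list(nms, nms))
  m
}

#' Write an FCS 3.1 list-mode file
#'
#' Writes float32 little-endian list-mode data with \code{$PnN}/\code{$PnS}
#' from the channel/marker names. \code{readFCS(writeFCS(x))} reproduces
#' values up to float32 rounding and names exactly. A ground-truth column,
#' if present, is not written (CSV export preserves it).
#'
#' @param events an \linkS4class{EventMatrix} with finite values and at
#'   least one channel.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeFCS <- function(events, path) {
  stopifnot(is(events, "EventMatrix"))
  v <- events@exprs
  if (ncol(v) < 1L) stop("at least one channel required")
  if (length(v) && any(!is.finite(v)))
    stop("validation error: non-finite values cannot be written to FCS")
  par <- ncol(v); tot <- nrow(v)
  kw <- c(
    "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
    "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
    "$BEGINDATA" = "%BEGIN%", "$ENDDATA" = "%END%",
    "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
    "$NEXTDATA" = "0", "$TOT" = as.character(tot), "$PAR" = as.character(par))
  for (i in seq_len(par)) {
    kw[sprintf("$P%dB", i)] <- "32"
    kw[sprintf("$P%dE", i)] <- "0,0"
    kw[sprintf("$P%dR", i)] <- "1048576"
    kw[sprintf("$P%dN", i)] <- colnames(v)[i]
    if (nzchar(events@markerNames[i]))
      kw[sprintf("$P%dS", i)] <- events@markerNames[i]
  }
  delim <- "\x1e"
  if (any(grepl(delim, kw, fixed = TRUE)) ||
      any(grepl(delim, names(kw), fixed = TRUE)))
    stop("keyword values may not contain the delimiter byte 0x1e")
  buildText <- function(beg, end) {
    kw["$BEGINDATA"] <- sprintf("%010d", beg)
    kw["$ENDDATA"] <- sprintf("%010d", end)
    paste0(delim, paste0(names(kw), delim, kw, delim, collapse = ""))
  }
  txt <- buildText(0, 0)
  textBeg <- 58L
  textEnd <- textBeg + nchar(txt, type = "bytes") - 1L
  nBytes <- 4L * tot * par
  dataBeg <- if (nBytes > 0) textEnd + 1L else 0L
  dataEnd <- if (nBytes > 0) dataBeg + nBytes - 1L else 0L
  txt <- buildText(dataBeg, dataEnd)  # placeholders were fixed-width

  hdrNum <- function(x) formatC(x, width = 8, flag = " ")
  hdr <- paste0("FCS3.1    ", hdrNum(textBeg), hdrNum(textEnd),
                hdrNum(if (dataEnd <= 99999999) dataBeg else 0),
                hdrNum(if (dataEnd <= 99999999) dataEnd else 0),
                hdrNum(0), hdrNum(0))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(hdr), con)
  writeBin(charToRaw(txt), con)
  if (nBytes > 0)
    writeBin(as.vector(t(v)), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read/write CSV event tables
#'
#' A fixture-friendly dialect: first header row holds channel names, an
#' optional second header row holds marker names (detected automatically on
#' read when its fields are non-numeric). Columns named \code{sample_id} and
#' \code{population} are treated as sample-origin and simulator ground-truth
#' labels, not channels.
#'
#' @param path file path.
#' @param sampleId default sample label when no \code{sample_id} column.
#' @return an \linkS4class{EventMatrix}, state \code{"raw"}.
#' @export
readEventsCSV <- function(path, sampleId = NULL) {
  if (is.null(sampleId)) sampleId <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  if (!length(lines)) stop("empty CSV: ", path)
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  markers <- rep("", length(header))
  dataStart <- 2L
  if (length(lines) >= 2) {
    second <- strsplit(lines[2], ",", fixed = TRUE)[[1]]
    numeric2 <- suppressWarnings(as.numeric(second))
    isMarkerRow <- any(is.na(numeric2) & nzchar(second))
    if (isMarkerRow) {
      markers[seq_along(second)] <- second
      dataStart <- 3L
    }
  }
  special <- tolower(header) %in% c("sample_id", "population")
  if (length(lines) >= dataStart) {
    body <- utils::read.csv(text = lines[dataStart:length(lines)],
                            header = FALSE, stringsAsFactors = FALSE)
    names(body) <- header
  } else {
    body <- as.data.frame(matrix(numeric(0), 0, length(header),
                                 dimnames = list(NULL, header)))
  }
  sid <- if ("sample_id" %in% tolower(header))
    as.character(body[[which(tolower(header) == "sample_id")[1]]]) else sampleId
  truth <- if ("population" %in% tolower(header))
    as.character(body[[which(tolower(header) == "population")[1]]]) else character(0)
  mat <- as.matrix(body[, !special, drop = FALSE])
  storage.mode(mat) <- "double"
  eventMatrix(mat, markerNames = markers[!special], sampleIds = sid,
              state = "raw", truth = truth)
}

#' @rdname readEventsCSV
#' @param events an \linkS4class{EventMatrix}.
#' @param markers write the marker-name second header row.
#' @export
writeEventsCSV <- function(events, path, markers = TRUE) {
  v <- events@exprs
  header <- c(colnames(v), "sample_id",
              if (length(events@truth)) "population")
  lines <- paste(header, collapse = ",")
  if (markers && any(nzchar(events@markerNames))) {
    mrow <- c(events@markerNames, "origin", if (length(events@truth)) "truth")
    lines <- c(lines, paste(mrow, collapse = ","))
  }
  cols <- c(lapply(seq_len(ncol(v)), function(j) fmtNum(v[, j])),
            list(events@sampleIds),
            if (length(events@truth)) list(events@truth))
  if (nrow(v)) lines <- c(lines, do.call(paste, c(cols, sep = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' Merge samples into one event table in panel channel order
#'
#' Row-concatenates samples in input order after matching each panel channel
#' within each sample - by marker name first (case-insensitive), falling
#' back to channel name - and reordering columns to panel order. All samples
#' must be in the same processing state; sample-origin labels are preserved.
#'
#' @param samples list of \linkS4class{EventMatrix} objects.
#' @param panel a \linkS4class{PanelDefinition}.
#' @return merged \linkS4class{EventMatrix} with columns named and ordered
#'   as in the panel.
#' @export
mergeEvents <- function(samples, panel) {
  stopifnot(length(samples) >= 1L)
  states <- vapply(samples, eventState, "")
  if (length(unique(states)) != 1L)
    stop("all samples must be in the same state; got: ",
         paste(unique(states), collapse = ", "))
  ch <- panel@channels
  pieces <- vector("list", length(samples))
  sids <- vector("list", length(samples))
  truths <- vector("list", length(samples))
  haveTruth <- TRUE
  for (s in seq_along(samples)) {
    x <- samples[[s]]
    idx <- .matchPanelChannels(x, ch, sampleLabel = .sampleLabel(x, s))
    m <- x@exprs[, idx, drop = FALSE]
    colnames(m) <- ch$channel
    pieces[[s]] <- m
    sids[[s]] <- x@sampleIds
    if (length(x@truth)) truths[[s]] <- x@truth else haveTruth <- FALSE
  }
  eventMatrix(do.call(rbind, pieces),
              markerNames = ch$marker,
              sampleIds = unlist(sids),
              state = states[1],
              truth = if (haveTruth) unlist(truths) else character(0))
}

.sampleLabel <- function(x, s) {
  u <- unique(x@sampleIds)
  if (length(u) == 1L) u else sprintf("sample %d", s)
}

.matchPanelChannels <- function(x, channels, sampleLabel) {
  xm <- tolower(x@markerNames)
  xc <- tolower(colnames(x@exprs))
  idx <- integer(nrow(channels))
  for (i in seq_len(nrow(channels))) {
    hit <- integer(0)
    if (nzchar(channels$marker[i])) hit <- which(xm == tolower(channels$marker[i]))
    if (!length(hit)) hit <- which(xc == tolower(channels$channel[i]))
    if (!length(hit) && nzchar(channels$marker[i]))
      hit <- which(xc == tolower(channels$marker[i]))
    if (!length(hit))
      stopWithClass("marrowSOM_channel_mismatch",
                    "sample '%s' is missing panel channel '%s' (marker '%s')",
                    sampleLabel, channels$channel[i], channels$marker[i])
    idx[i] <- hit[1]
  }
  idx
}

#' Filter events by a predicate (optional pre-gating hook)
#'
#' All events are treated as input by default throughout the package; this
#' row filter is the hook for debris/doublet exclusion when desired.
#'
#' @param events an \linkS4class{EventMatrix}.
#' @param keep logical vector (one per event) or a function taking the
#'   EventMatrix and returning one.
#' @return the filtered \linkS4class{EventMatrix}.
#' @export
filterEvents <- function(events, keep) {
  if (is.function(keep)) keep <- keep(events)
  stopifnot(is.logical(keep), length(keep) == nEvents(events))
  events[which(keep)]
}
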