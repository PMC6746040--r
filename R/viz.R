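#' @include AllClasses.R
NULL

.FLAG_COLORS <- c(none = "#B0B0B0", excess = "#D4A017", deficit = "#4575B4")

#' Render a reference MST
#'
#' Draws the template's MST with node glyph area strictly increasing with
#' event count, colored by node label, comparison flag, or count. The
#' coordinate/size/color table behind the plot is returned and written
#' alongside the image, so display assertions never need the raster.
#'
#' @param template a \linkS4class{ReferenceTemplate} with layout.
#' @param report optional \linkS4class{ComparisonReport} or
#'   \linkS4class{MappedSample}; node counts (and flags) then come from the
#'   patient sample instead of the merged normals.
#' @param file output image path (.png), or \code{NULL} to skip rendering.
#' @param colorBy \code{"label"}, \code{"flag"} or \code{"count"}.
#' @param tableFile path for the coordinates table (default:
#'   \code{file} with a \code{.csv} extension).
#' @return the coordinates table (one row per node: \code{node}, \code{x},
#'   \code{y}, \code{count}, \code{radius}, \code{color}, \code{label},
#'   \code{flag}), invisibly when \code{file} is given.
#' @export
renderMST <- function(template, report = NULL, file = NULL,
                      colorBy = c("label", "flag", "count"),
                      tableFile = NULL) {
  colorBy <- match.arg(colorBy)
  lay <- template@tree@layout
  if (!nrow(lay)) stop("template has no layout")
  n <- nNodes(template)
  counts <- template@nodeStats$count
  flag <- rep("none", n)
  if (is(report, "MappedSample")) {
    counts <- round(occupancy(report) * report@eventCount)
  } else if (is(report, "ComparisonReport")) {
    # occupancy fractions rescaled to the merged-cohort count range so the
    # size legend stays comparable across the side-by-side displays
    counts <- round(report@nodeTable$occupancy * sum(template@nodeStats$count))
    flag <- report@nodeTable$flag
  }
  labels <- vapply(nodeLabels(template), function(x)
    paste(x, collapse = ";"), "")
  if (!length(labels)) labels <- rep("", n)
  ## strictly monotone size mapping: radius ~ sqrt(count), small floor
  radius <- 0.02 + 0.12 * sqrt(counts) / sqrt(max(counts, 1))
  color <- switch(colorBy,
    flag = unname(.FLAG_COLORS[flag]),
    count = grDevices::gray(1 - 0.8 * counts / max(counts, 1)),
    label = {
      labs <- unique(labels[nzchar(labels)])
      pal <- if (length(labs)) grDevices::hcl.colors(max(3L, length(labs)),
                                                     "Dark 3") else character(0)
      out <- rep("#B0B0B0", n)
      for (k in seq_along(labs)) out[labels == labs[k]] <- pal[k]
      out
    })
  tab <- data.frame(node = seq_len(n), x = lay[, 1], y = lay[, 2],
                    count = counts, radius = radius, color = color,
                    label = labels, flag = flag)
  if (!is.null(file)) {
    if (is.null(tableFile)) tableFile <- sub("\\.[^.]*$", ".csv", file)
    utils::write.csv(tab, tableFile, row.names = FALSE)
    grDevices::png(file, width = 900, height = 900, res = 120)
    on.exit(grDevices::dev.off())
    graphics::par(mar = c(1, 1, 2, 1))
    graphics::plot(lay, type = "n", axes = FALSE, xlab = "", ylab = "",
                   main = sprintf("%s reference MST (%d nodes)",
                                  template@panel@name, n))
    e <- template@tree@edges
    graphics::segments(lay[e$from, 1], lay[e$from, 2],
                       lay[e$to, 1], lay[e$to, 2], col = "grey70")
    sc <- diff(range(lay[, 1]))
    graphics::symbols(lay[, 1], lay[, 2], circles = radius * sc,
                      inches = FALSE, add = TRUE, bg = color, fg = "grey30")
    invisible(tab)
  } else tab
}
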