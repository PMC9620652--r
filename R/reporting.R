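#' @importFrom ggplot2 ggplot aes geom_point geom_line geom_col
#'   scale_x_log10 labs theme_bw facet_grid theme element_text ggsave
NULL

utils::globalVariables(".data")

# write the arrays behind a figure next to it, so tests and reruns can
# assert on data rather than raster bytes
writeSidecar <- function(data, file) {
  jsonlite::write_json(data, paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(NULL)
}

#' Cohort scatter of GCVsig score versus mutation count
#'
#' Score against mutation count on a log x-axis, with the 1% FDR cutoff
#' curves overlaid and called positives highlighted.
#'
#' @param calls Calls data.frame from [runCohort()] (non-empty).
#' @param curve18 SBS18 [CutoffCurve-class].
#' @param curve38 Optional SBS38 [CutoffCurve-class].
#' @param file Optional output path (e.g. `.png`); a JSON sidecar of the
#'   plotted arrays is written alongside it.
#' @return The ggplot object, invisibly, with the plotted data in
#'   `attr(, "plotData")`.
#' @export
plotCohortScatter <- function(calls, curve18, curve38 = NULL, file = NULL) {
  if (nrow(calls) == 0L) stop("empty calls table")
  pts <- calls[calls$n >= 1, , drop = FALSE]
  pts$status <- ifelse(pts$positive, "GCVsig positive",
                       ifelse(pts$evaluable, "negative", "not evaluable"))
  curves <- data.frame(n = curve18@countsGrid, cutoff = curve18@cutoffs,
                       null = curve18@nullSignature)
  if (!is.null(curve38))
    curves <- rbind(curves,
                    data.frame(n = curve38@countsGrid,
                               cutoff = curve38@cutoffs,
                               null = curve38@nullSignature))
  p <- ggplot(pts, aes(x = .data$n, y = .data$gcv_score)) +
    geom_line(data = curves,
              aes(x = .data$n, y = .data$cutoff, linetype = .data$null),
              colour = "grey30", inherit.aes = FALSE) +
    geom_point(aes(colour = .data$status), size = 1.4, alpha = 0.8) +
    scale_x_log10() +
    labs(x = "mutation count", y = "GCVsig contribution score",
         colour = NULL, linetype = "1% FDR null") +
    theme_bw()
  plotData <- list(points = pts[, c("sample_id", "n", "gcv_score",
                                    "positive", "evaluable")],
                   curves = curves)
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 7, height = 4.5, dpi = 150)
    writeSidecar(plotData, file)
  }
  attr(p, "plotData") <- plotData
  invisible(p)
}

#' SBS96 spectrum bar plot
#'
#' The standard 96-bar trinucleotide spectrum, grouped by the six
#' substitution classes in canonical order.
#'
#' @param spectrum Named 96-vector of channel counts (total > 0).
#' @param file Optional output path; a JSON sidecar of the plotted arrays is
#'   written alongside it.
#' @return The ggplot object, invisibly, with plotted data in
#'   `attr(, "plotData")`.
#' @export
plotSpectrum <- function(spectrum, file = NULL) {
  stopifnot(length(spectrum) == 96L)
  if (sum(spectrum) <= 0) stop("empty spectrum")
  if (is.null(names(spectrum))) names(spectrum) <- SBS96_CHANNELS
  spectrum <- spectrum[SBS96_CHANNELS]
  parts <- channelParts(SBS96_CHANNELS)
  d <- data.frame(
    channel = factor(SBS96_CHANNELS, levels = SBS96_CHANNELS),
    context = paste0(parts$p5, parts$ref, parts$p3),
    class = factor(paste0(parts$ref, ">", parts$alt),
                   levels = PYRIMIDINE_SUBS),
    count = as.numeric(spectrum))
  p <- ggplot(d, aes(x = .data$channel, y = .data$count,
                     fill = .data$class)) +
    geom_col() +
    facet_grid(. ~ class, scales = "free_x") +
    labs(x = NULL, y = "mutations") +
    theme_bw() +
    theme(axis.text.x = element_text(angle = 90, size = 4),
          legend.position = "none")
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 9, height = 3, dpi = 150)
    writeSidecar(d, file)
  }
  attr(p, "plotData") <- d
  invisible(p)
}
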