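#' Render ratio maps as blue-to-red heatmap images
#'
#' Maps finite ratio values onto a perceptually ordered blue (basal) to red
#' (active) lookup table over `lut_range`; out-of-range values clip to the
#' endpoints and `NaN` pixels render as the background colour.  One PNG is
#' written per frame.
#'
#' @param rmap a [ratio_map()].
#' @param lut_range numeric length-2: ratio values mapped to the LUT ends.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @param na_color background colour for `NaN` pixels.
#' @return character vector of written file paths, invisibly.
#' @export
render_ratio_heatmap <- function(rmap, lut_range = c(0.5, 2), dir = ".",
                                 prefix = "ratio", na_color = "black") {
  stopifnot(inherits(rmap, "ratio_map"), length(lut_range) == 2,
            lut_range[2] > lut_range[1])
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lut <- grDevices::colorRampPalette(
    c("#0000B0", "#0080FF", "#00E0E0", "#E8E800", "#FF8000", "#D00000"))(256)
  lut_rgb <- grDevices::col2rgb(lut) / 255
  na_rgb <- grDevices::col2rgb(na_color)[, 1] / 255
  d <- dim(rmap$ratio)
  paths <- character(d[3])
  for (t in seq_len(d[3])) {
    fr <- rmap$ratio[, , t]
    idx <- (fr - lut_range[1]) / diff(lut_range)
    idx <- pmin(pmax(idx, 0), 1)
    bin <- as.integer(round(idx * 255)) + 1L
    img <- array(0, c(d[1], d[2], 3))
    for (k in 1:3) {
      plane <- lut_rgb[k, bin]
      plane[!is.finite(fr)] <- na_rgb[k]
      img[, , k] <- matrix(plane, d[1], d[2])
    }
    paths[t] <- file.path(dir, sprintf("%s_%03d.png", prefix, t))
    png::writePNG(img, paths[t])
  }
  invisible(paths)
}

#' Score histogram for a scored cohort
#'
#' The event-count histogram of the internalization score with the bound
#' (below threshold, blue) and internalized (at or above, red) regions
#' shaded, mirroring how the score distribution is read.
#'
#' @param scored tibble from [score_events()].
#' @param tau threshold drawn as the class boundary.
#' @param binwidth histogram bin width in score units.
#' @return a ggplot object.
#' @export
plot_score_histogram <- function(scored, tau = 2, binwidth = 0.25) {
  df <- dplyr::filter(scored, is.finite(.data$score),
                      .data$label_pred %in% c("bound", "internalized"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, fill = .data$score >= tau)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0, color = "grey20") +
    ggplot2::geom_vline(xintercept = tau, linetype = "dashed") +
    ggplot2::scale_fill_manual(
      values = c(`FALSE` = "#4575B4", `TRUE` = "#D73027"),
      labels = c(`FALSE` = "bound", `TRUE` = "internalized"),
      name = NULL) +
    ggplot2::labs(x = "internalization score s", y = "events") +
    ggplot2::theme_minimal()
}

#' @describeIn activation_trace Plot the activation ratio over time, with the
#'   membrane and cytosol means alongside.
#' @param object an `activation_trace` tibble.
#' @param ... unused.
#' @export
autoplot.activation_trace <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object, c("membrane_mean", "cytosol_mean", "activation_ratio"),
    names_to = "series", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$time_min, .data$value,
                                     color = .data$series)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(na.rm = TRUE, size = 1) +
    ggplot2::labs(x = "time (min)", y = NULL, color = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
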