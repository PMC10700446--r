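# Per-participant diagnostic plot.
#
# One row per grapheme: the symbol is printed once per trial in the trial's
# response color on a mid-gray background (so both very light and very dark
# responses stay visible), next to a bar giving the grapheme's consistency
# score. This is the plot a rater inspects to judge whether responses are
# too homogeneous, too sparse, or suspiciously light.

#' Diagnostic plot of one participant's responses and scores
#'
#' Left panel: the inducer symbol rendered once per trial in the response
#' color; missing responses are drawn as an open cross. Right panel: a bar
#' per grapheme whose length is the grapheme's consistency score under
#' `config` (no bar for unscorable graphemes); when the config carries a
#' cutoff, a dashed line marks it.
#'
#' @param participant A `participant` with at least one grapheme.
#' @param config A [scoring_config()] controlling the score scale.
#' @param out_path Optional output file path ending in `.png` or `.svg`; when
#'   given, the figure is written there.
#' @param width,height Device size in inches; height defaults to scale with
#'   the number of graphemes.
#' @param dpi Resolution for PNG output.
#' @return The ggplot object (patchwork), invisibly if written to file.
#' @export
plot_participant <- function(participant, config = scoring_config(),
                             out_path = NULL, width = 7, height = NULL,
                             dpi = 150) {
  stopifnot(inherits(participant, "participant"))
  gs <- participant$graphemes
  if (!length(gs)) {
    stop("participant '", participant$id, "' has no graphemes to plot",
         call. = FALSE)
  }
  symbols <- vapply(gs, function(g) g$symbol, character(1))
  trials <- lapply(gs, function(g) g$hex)
  resp <- data.frame(
    symbol = factor(rep(symbols, lengths(trials)), levels = rev(symbols)),
    trial = unlist(lapply(lengths(trials), seq_len), use.names = FALSE),
    hex = unlist(trials, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  bars <- data.frame(
    symbol = factor(symbols, levels = rev(symbols)),
    score = vapply(gs, grapheme_score, numeric(1), config = config)
  )

  trial <- symbol <- hex <- score <- NULL  # silence R CMD check notes
  p_resp <- ggplot2::ggplot(resp, ggplot2::aes(x = trial, y = symbol)) +
    ggplot2::geom_text(
      data = resp[!is.na(resp$hex), ],
      ggplot2::aes(label = symbol, colour = I(hex)),
      size = 5, fontface = "bold"
    ) +
    ggplot2::geom_point(
      data = resp[is.na(resp$hex), ],
      shape = 4, colour = "white", size = 3
    ) +
    ggplot2::scale_x_continuous(breaks = unique(resp$trial),
                                expand = ggplot2::expansion(add = 0.5)) +
    ggplot2::labs(x = "trial", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      panel.background = ggplot2::element_rect(fill = "grey50",
                                               colour = NA),
      panel.grid = ggplot2::element_blank()
    )

  p_bars <- ggplot2::ggplot(bars[!is.na(bars$score), ],
                            ggplot2::aes(x = score, y = symbol)) +
    ggplot2::geom_col(fill = "grey30", width = 0.7) +
    ggplot2::scale_y_discrete(drop = FALSE) +
    ggplot2::labs(
      x = sprintf("consistency score (%s, %s)",
                  config$metric, config$color_space),
      y = NULL
    ) +
    ggplot2::theme_minimal()
  if (!is.null(config$cutoff)) {
    p_bars <- p_bars +
      ggplot2::geom_vline(xintercept = config$cutoff, linetype = "dashed",
                          colour = "red3")
  }

  plt <- patchwork::wrap_plots(p_resp, p_bars, widths = c(1, 2)) +
    patchwork::plot_annotation(title = paste("Participant", participant$id))

  if (is.null(out_path)) return(plt)
  if (is.null(height)) height <- max(2, 0.35 * length(gs) + 1.2)
  ext <- tolower(sub(".*\\.", "", out_path))
  if (ext == "png") {
    grDevices::png(out_path, width = width, height = height, units = "in",
                   res = dpi, type = "cairo")
  } else if (ext == "svg") {
    grDevices::svg(out_path, width = width, height = height)
  } else {
    stop("unsupported image extension '.", ext, "' (use .png or .svg)",
         call. = FALSE)
  }
  on.exit(grDevices::dev.off())
  print(plt)
  invisible(plt)
}
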