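#' Bar chart of log model evidences relative to the null model
#'
#' @param bms a `bms_result`.
#' @return a ggplot object.
#' @export
plot_bms <- function(bms) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  tb <- bms$table
  tb$model <- factor(tb$model, levels = tb$model)
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$model, y = .data$rel_F)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "log evidence relative to null") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Per-cell posterior gain modulations with 95% intervals
#'
#' One panel per modulated source; negative values mean reduced
#' self-inhibition (increased excitability).
#'
#' @param gain_table output of [extract_gain_modulations()].
#' @return a ggplot object.
#' @export
plot_gain_modulations <- function(gain_table) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  gt <- gain_table
  gt$group <- factor(gt$group, levels = c("controls", "relatives",
                                          "patients"))
  ggplot2::ggplot(gt, ggplot2::aes(x = .data$group, y = .data$gain,
                                   fill = .data$condition)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lo,
                                        ymax = .data$hi),
                           position = ggplot2::position_dodge(0.8),
                           width = 0.2) +
    ggplot2::facet_wrap(~source) +
    ggplot2::labs(x = NULL, y = "log scaling of sp self-inhibition") +
    ggplot2::theme_minimal()
}
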