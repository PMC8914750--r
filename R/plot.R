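# ggplot2 figures for traces and confusion matrices.

#' Plot measured versus estimated grip force
#'
#' @param trace A `grip_trace` data frame.
#' @return A ggplot object.
#' @export
plot_grip_trace <- function(trace) {
  df <- data.frame(t = rep(trace$t, 2),
                   force = c(trace$Fm, trace$Fp),
                   series = rep(c("measured", "estimated"), each = nrow(trace)))
  ggplot2::ggplot(df, ggplot2::aes(x = t, y = force, colour = series)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(x = "time (s)", y = "grip force (N)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a wrist-angle confusion matrix
#'
#' @param confusion A 3x3 confusion matrix (rows = true class).
#' @return A ggplot object.
#' @export
plot_confusion_matrix <- function(confusion) {
  df <- as.data.frame(as.table(confusion))
  names(df) <- c("true", "predicted", "count")
  ggplot2::ggplot(df, ggplot2::aes(x = predicted, y = true, fill = count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = count)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted angle (deg)", y = "true angle (deg)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

utils::globalVariables(c("t", "force", "series", "predicted", "true", "count"))
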