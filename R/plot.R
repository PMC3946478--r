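# Plots: index-series trajectories and verification overlays.

#' Plot the index series of an iteration trace
#'
#' Dunn and maximum-diameter values against the iteration number, one panel
#' per index.  A valid run shows Dunn rising to its terminal maximum and the
#' diameter falling to its terminal minimum.
#'
#' @param object A `"cluster_trace"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cluster_trace
#' @export
autoplot.cluster_trace <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::select("iteration", "dunn", "diam") |>
    tidyr::pivot_longer(c("dunn", "diam"), names_to = "index",
                        values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(x = "iteration", y = "index value",
                  title = sprintf("%s run, %d iterations", object$algorithm,
                                  length(object$records)))
}

#' Plot a verification outcome over its trace
#'
#' The trace's index series with the cause iterations (the error trace minus
#' the satisfying sub-trace) shaded.
#'
#' @param trace The verified `"cluster_trace"`.
#' @param report The matching `"cluster_verification"` from [verify_trace()].
#' @return A ggplot object.
#' @export
plot_verification <- function(trace, report) {
  p <- autoplot(trace)
  cause_iters <- as.integer(sub("^S", "", report$real_causes))
  if (length(cause_iters)) {
    p <- p + ggplot2::geom_vline(xintercept = cause_iters,
                                 linetype = "dashed", colour = "red")
  }
  p + ggplot2::labs(
    subtitle = if (report$valid) "verdict: valid"
               else sprintf("verdict: invalid (causes: %s)",
                            paste(report$real_causes, collapse = ", ")))
}

#' Heat map of a confusion matrix
#'
#' @param object A `"clust_confusion"` from [confusion_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot clust_confusion
#' @export
autoplot.clust_confusion <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cluster, y = .data$class,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::labs(x = "cluster", y = "class")
}
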