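# ggplot2 is suggested, not imported: plots are a convenience layer.
need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the ggplot2 package", call. = FALSE)
  }
}

utils::globalVariables(c("round", "mean_diff", "cohort", "se",
                         "x_m", "y_m", "search_time_s", "hemispace"))

#' Plot the mean level-difference trajectory with standard-error bars
#'
#' @param trajectory Output of [level_difference_trajectory()], or the
#'   cohort-stacked table from [analyze_sessions()].
#' @return A ggplot object.
#' @export
plot_level_trajectory <- function(trajectory) {
  need_ggplot()
  aes <- ggplot2::aes
  has_cohort <- "cohort" %in% names(trajectory)
  ggplot2::ggplot(
    trajectory,
    if (has_cohort) aes(x = round, y = mean_diff, colour = cohort,
                        group = cohort)
    else aes(x = round, y = mean_diff)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(aes(ymin = mean_diff - se,
                               ymax = mean_diff + se), width = 0.2) +
    ggplot2::labs(x = "Round", y = "Level difference vs starting level")
}

#' Plot a controller hand trace in the 2 m x 2 m workspace
#'
#' @param trace Data.frame `(t_s, x_m, y_m)` or a session record.
#' @return A ggplot object.
#' @export
plot_hand_trace <- function(trace) {
  need_ggplot()
  if (inherits(trace, "session_record")) trace <- trace$hand_trace
  ggplot2::ggplot(trace, ggplot2::aes(x = x_m, y = y_m)) +
    ggplot2::geom_path(alpha = 0.4, colour = "steelblue") +
    ggplot2::coord_fixed(xlim = c(-1, 1), ylim = c(-1, 1)) +
    ggplot2::labs(x = "x (m)", y = "y (m)")
}

#' Scatter of neglect severity against per-hemispace search time
#'
#' @param metrics [session_metrics()] table with a `coc` column.
#' @return A ggplot object with one panel per hemispace.
#' @export
plot_severity_scatter <- function(metrics) {
  need_ggplot()
  m <- metrics[!is.na(metrics$coc), ]
  long <- rbind(
    data.frame(coc = m$coc, search_time_s = m$left_search_time_s,
               hemispace = "left"),
    data.frame(coc = m$coc, search_time_s = m$right_search_time_s,
               hemispace = "right"))
  ggplot2::ggplot(long, ggplot2::aes(x = coc, y = search_time_s)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::facet_wrap(~hemispace, scales = "free_y") +
    ggplot2::labs(x = "Center of Cancellation",
                  y = "Mean search time (s)")
}
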