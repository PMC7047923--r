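#' Trajectory plot of a simulated feature
#'
#' Per-subject abundance trajectories (thin lines) with group mean
#' trajectories overlaid (thick lines), one colour per arm. Plots the
#' observed outcome `Y_obs` by default so induced missingness (e.g. zeros) is
#' visible.
#'
#' @param dataset A `sim_feature` from [simulate_feature()].
#' @param observed Plot `Y_obs` (default) or the complete outcome `Y`.
#' @return A ggplot object.
#' @export
plot_trajectories <- function(dataset, observed = TRUE) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_trajectories requires the 'ggplot2' package", call. = FALSE)
  }
  stopifnot(inherits(dataset, "sim_feature"))
  rec <- dataset$records
  rec$value <- if (observed) rec$Y_obs else rec$Y
  rec <- rec[!is.na(rec$value), , drop = FALSE]
  means <- stats::aggregate(value ~ time + group, data = rec, FUN = mean)
  ggplot2::ggplot(rec, ggplot2::aes(x = .data$time, y = .data$value,
                                    colour = .data$group)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$ID), alpha = 0.35,
                       linewidth = 0.3) +
    ggplot2::geom_line(data = means,
                       ggplot2::aes(group = .data$group),
                       linewidth = 1.2) +
    ggplot2::labs(x = "time", y = if (observed) "abundance (observed)"
                                  else "abundance",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
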