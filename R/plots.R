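# ggplot2 autoplot methods for the package's result types.

#' @describeIn fret_histogram Plot the histogram (E clamped to the
#'   histogram range for display).
#' @param object,x,... autoplot arguments.
#' @export
autoplot.fret_histogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(width = attr(object, "binwidth"), fill = "grey60") +
    ggplot2::labs(x = "FRET efficiency", y = "Count",
                  title = paste0(sub("_", "-", attr(object, "mode")),
                                 " FRET histogram")) +
    ggplot2::theme_classic()
}

#' @describeIn fit_fret_mixture Overlay the fitted mixture and its
#'   components on the histogram.
#' @param object,... autoplot arguments.
#' @export
autoplot.fret_mixture_fit <- function(object, ...) {
  h <- object$hist
  bw <- attr(h, "binwidth")
  n <- attr(h, "n_values")
  grid <- seq(min(h$mid), max(h$mid), length.out = 400)
  comp <- purrr::map_dfr(seq_len(nrow(object$components)), function(j) {
    w <- object$components$area[j] / 100
    tibble::tibble(component = factor(j), x = grid,
                   y = n * bw * w * dnorm(grid, object$components$mean[j],
                                          object$components$sd[j]))
  })
  total <- dplyr::summarise(comp, y = sum(.data$y), .by = "x")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(width = bw, fill = "grey80") +
    ggplot2::geom_line(data = comp,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    colour = .data$component)) +
    ggplot2::geom_line(data = total, ggplot2::aes(x = .data$x, y = .data$y),
                       linewidth = 0.8) +
    ggplot2::labs(x = "FRET efficiency", y = "Count",
                  subtitle = sprintf("R² = %.3f", object$r_squared)) +
    ggplot2::theme_classic()
}

#' @describeIn build_tdp Heat-map of the transition density with the
#'   diagonal marked.
#' @param object,... autoplot arguments.
#' @export
autoplot.fret_tdp <- function(object, ...) {
  df <- tibble::tibble(
    e_from = rep(object$x, times = length(object$y)),
    e_to = rep(object$y, each = length(object$x)),
    density = as.vector(object$density))
  ggplot2::ggplot(df, ggplot2::aes(.data$e_from, .data$e_to,
                                   fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "white",
                         linetype = 2, linewidth = 0.3) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Initial FRET efficiency", y = "Final FRET efficiency",
                  fill = "Density") +
    ggplot2::theme_classic()
}

#' @describeIn build_survival Step plot of the survival fraction.
#' @param object,... autoplot arguments.
#' @export
autoplot.survival_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_s, .data$fraction)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Time (s)", y = "Surviving fraction",
                  title = attr(object, "condition")) +
    ggplot2::theme_classic()
}

#' @describeIn decode_path FRET trace with the decoded state path overlaid.
#' @param object,... autoplot arguments.
#' @export
autoplot.state_path <- function(object, ...) {
  df <- object$path
  df$e_obs <- object$model$e[seq_len(nrow(df))]
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$e_obs)) +
    ggplot2::geom_line(colour = "steelblue", linewidth = 0.3) +
    ggplot2::geom_step(ggplot2::aes(y = .data$e_state), colour = "red") +
    ggplot2::labs(x = "Time (s)", y = "FRET efficiency") +
    ggplot2::theme_classic()
}

#' Plot a two-channel intensity trace
#'
#' Donor and acceptor counts against time for one molecule, the standard
#' raw-trace view used to spot single-step bleaching.
#'
#' @param traces Trace table.
#' @param molecule Molecule id to plot.
#' @return A ggplot object.
#' @export
plot_trace <- function(traces, molecule = traces$molecule_id[1]) {
  df <- traces |>
    dplyr::filter(.data$molecule_id == molecule) |>
    tidyr::pivot_longer(c("donor_counts", "acceptor_counts"),
                        names_to = "channel", values_to = "counts")
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$counts,
                                   colour = .data$channel)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(donor_counts = "forestgreen",
                                            acceptor_counts = "firebrick")) +
    ggplot2::labs(x = "Time (s)", y = "Counts", colour = NULL) +
    ggplot2::theme_classic()
}
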