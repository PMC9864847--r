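#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_hline
#'   geom_vline labs theme_minimal facet_wrap scale_colour_viridis_d
NULL

#' @export
ggplot2::autoplot

#' Plot per-moiety protrusion benchmarks over time
#'
#' @param object a [protrusion_series()] result.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.protrusion_benchmark <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = .data$time, y = .data$protrusion,
             colour = factor(.data$moiety, levels = moiety_levels()))) +
    geom_line() +
    labs(x = "time (ns)", y = "protrusion (Å)", colour = "moiety") +
    theme_minimal()
}

#' Plot a residue burial series against moiety benchmarks
#'
#' @param object a [com_z_series()] result.
#' @param benchmark optional [protrusion_series()] whose per-moiety
#'   averages are drawn as horizontal rulers.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.burial_series <- function(object, benchmark = NULL, ...) {
  p <- ggplot(as_tibble(object), aes(x = .data$time, y = .data$z)) +
    geom_line(colour = "steelblue") +
    geom_hline(yintercept = attr(object, "average"), linetype = 2) +
    labs(x = "time (ns)",
         y = sprintf("residue %s COM z (Å)", attr(object, "residue"))) +
    theme_minimal()
  if (!is.null(benchmark)) {
    s <- tidy(benchmark)
    p <- p + geom_hline(data = s,
                        aes(yintercept = .data$benchmark,
                            colour = .data$moiety))
  }
  p
}

#' Plot stage segmentation diagnostics
#'
#' Smoothed centre and near-periphery contact occupancy with the detected
#' stage boundaries.
#'
#' @param object a [segment_stages()] result.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.stage_segmentation <- function(object, ...) {
  d <- object$diagnostics$smoothed |>
    tidyr::pivot_longer(c("center", "periphery_near"),
                        names_to = "zone", values_to = "occupancy")
  p <- ggplot(d, aes(x = .data$time, y = .data$occupancy,
                     colour = .data$zone)) +
    geom_line() +
    geom_hline(yintercept = object$diagnostics$min_occupancy,
               linetype = 3) +
    labs(x = "time (ns)", y = "smoothed contact occupancy") +
    theme_minimal()
  for (tt in c(object$t_detach, object$t_stabilize)) {
    if (is.finite(tt)) p <- p + geom_vline(xintercept = tt, linetype = 2)
  }
  p
}

#' Plot a residue travel trail in the xy plane, coloured by depth
#'
#' @param trail a [travel_trail()] result.
#' @return A ggplot.
#' @export
plot_trail <- function(trail) {
  ggplot(as_tibble(trail), aes(x = .data$x, y = .data$y,
                               colour = .data$z)) +
    geom_point(size = 0.8) +
    labs(x = "x (Å)", y = "y (Å)", colour = "z (Å)") +
    theme_minimal()
}

#' Plot per-zone solvation series
#'
#' @param report a [zone_solvation_report()] result.
#' @param what `"waters"` or `"sasa"`.
#' @return A ggplot.
#' @export
plot_zone_solvation <- function(report, what = c("waters", "sasa")) {
  what <- match.arg(what)
  ggplot(report$series,
         aes(x = .data$time, y = .data[[what]],
             colour = factor(.data$zone, levels = zone_levels()))) +
    geom_line() +
    labs(x = "time (ns)",
         y = if (what == "waters") "water molecules" else "SASA (Å²)",
         colour = "zone") +
    theme_minimal()
}
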