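#' Plot a simulated trajectory
#'
#' Draws subpopulation densities over time, one colour per subpopulation.
#' For serial-transfer trajectories, batch boundaries are marked.
#'
#' @param object A `pc_trajectory`.
#' @param log10 Plot densities on a log10 axis (zeros dropped).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pc_trajectory <- function(object, log10 = FALSE, ...) {
  comp <- model_components(attr(object, "model"))
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = dplyr::all_of(comp),
                              names_to = "population",
                              values_to = "density")
  long$population <- factor(long$population, levels = c("f", "p", "c", "q"),
                            labels = c("plasmid-free (f)", "plasmid (p)",
                                       "chrCM (c)", "plaCM (q)"))
  gg <- ggplot2::ggplot(long,
                        ggplot2::aes(x = .data$time_h, y = .data$density,
                                     colour = .data$population)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (h)", y = "density (fraction of K)",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (log10) gg <- gg + ggplot2::scale_y_log10()
  if (identical(attr(object, "regime"), "serial_transfer")) {
    proto <- attr(object, "protocol")
    if (!is.null(proto)) {
      cuts <- proto$hours_per_transfer * seq_len(proto$n_transfers - 1)
      gg <- gg + ggplot2::geom_vline(xintercept = cuts, linetype = "dotted",
                                     colour = "grey70")
    }
  }
  gg
}

#' Plot a phase-region scan
#'
#' Tile plot of region labels over the conjugation-rate grid from
#' [phase_region_scan()], with log-scaled axes.
#'
#' @param object A `pc_region_scan`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pc_region_scan <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$gamma_p, y = .data$gamma_cm,
                               fill = .data$label)) +
    ggplot2::geom_tile() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "gamma_p (dimensionless)",
                  y = "gamma_cm (dimensionless)", fill = "region") +
    ggplot2::theme_minimal()
}

#' Plot an RPS reduction scan
#'
#' @param object A `pc_rps_scan` from [rps_scan()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pc_rps_scan <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$coexists <- factor(df$coexists, c(FALSE, TRUE),
                        c("no coexistence", "f, p, q coexist"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$reduction, y = .data$coexists)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::scale_x_log10(breaks = df$reduction) +
    ggplot2::labs(x = "fold-reduction of gamma_q relative to gamma_p",
                  y = NULL) +
    ggplot2::theme_minimal()
}
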