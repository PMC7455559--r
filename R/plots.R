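#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_ribbon
#'   geom_col facet_wrap labs theme_minimal
NULL

#' Plot a per-carbon order-parameter profile
#'
#' @param object An `order_profile` from [scd_per_carbon()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.order_profile <- function(object, ...) {
  ggplot(object, aes(x = .data$carbon, y = .data$scd,
                     colour = .data$chain)) +
    geom_line() + geom_point() +
    labs(x = "acyl carbon (1 = ester end)", y = expression(S[CD]),
         colour = "chain") +
    theme_minimal()
}

#' Plot shell-averaged order parameters vs distance from the protein
#'
#' @param object A `shell_profile` from [shell_average_scd()].
#' @param carbons Carbon range averaged per shell (default 4:11).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.shell_profile <- function(object, carbons = 4:11, ...) {
  df <- dplyr::filter(object, .data$carbon %in% carbons, .data$n > 0)
  df <- dplyr::summarise(
    dplyr::group_by(df, .data$shell, .data$r_inner, .data$r_outer,
                    .data$chain),
    scd = mean(.data$scd), .groups = "drop")
  ggplot(df, aes(x = (.data$r_inner + .data$r_outer) / 2, y = .data$scd,
                 colour = .data$chain)) +
    geom_line() + geom_point() +
    labs(x = "distance from protein surface (Å)",
         y = expression(mean ~ S[CD] ~ "(carbons 4-11)"),
         colour = "chain") +
    theme_minimal()
}

#' Plot a lipid state time series as colored bars
#'
#' @param object A `state_series` from [state_timeseries()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.state_series <- function(object, ...) {
  ggplot(object, aes(x = .data$time_ns, y = factor(.data$lipid),
                     fill = .data$state)) +
    ggplot2::geom_tile() +
    labs(x = "time (ns)", y = "lipid", fill = "state") +
    theme_minimal()
}

#' Plot a state census as a bar chart
#'
#' @param object A [state_census()] tibble (plain tibble accepted).
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_state_census <- function(object, ...) {
  ggplot(object, aes(x = stats::reorder(.data$state, -.data$fraction),
                     y = .data$fraction)) +
    geom_col() +
    labs(x = "configuration state", y = "occupancy fraction") +
    theme_minimal()
}

#' Plot an RMSF profile with its confidence band
#'
#' @param object An `rmsf_profile` from [rmsf_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rmsf_profile <- function(object, ...) {
  p <- ggplot(object, aes(x = .data$residue, y = .data$mean_rmsf))
  if (all(object$ci_defined)) {
    p <- p + geom_ribbon(aes(ymin = .data$ci_low, ymax = .data$ci_high),
                         alpha = 0.25)
  }
  p + geom_line() +
    labs(x = "residue position", y = "r.m.s.f. (Å)") +
    theme_minimal()
}
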