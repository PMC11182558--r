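# ggplot2 visualisation of trajectories and sweeps.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point labs
#' @export
ggplot2::autoplot

#' Plot a trajectory
#'
#' Evolution curves of the opinion compartments over time.
#'
#' @param object,trajectory A [run_gp()] trajectory.
#' @param compartments Which stocks to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' autoplot(run_gp(gp_config(horizon = 40)))
#' @method autoplot gp_trajectory
#' @export
autoplot.gp_trajectory <- function(object,
                                   compartments = c("P", "PI", "N", "NI",
                                                    "NE", "NIN"),
                                   ...) {
  check_compartment(object, compartments)
  long <- tidyr::pivot_longer(
    as_tibble(object)[, c("t", compartments)],
    -"t", names_to = "compartment", values_to = "persons"
  )
  long$compartment <- factor(long$compartment, levels = compartments)
  ggplot(long, aes(x = .data$t, y = .data$persons,
                   colour = .data$compartment)) +
    geom_line() +
    labs(x = "time (days)", y = "users (persons)", colour = NULL,
         title = "Opinion-field evolution")
}

#' @rdname autoplot.gp_trajectory
#' @export
plot_trajectory <- function(trajectory, ...) {
  autoplot.gp_trajectory(trajectory, ...)
}

#' Plot a sensitivity sweep
#'
#' Peak of the negative-extreme stock (the polarization risk
#' indicator) against the swept parameter value.
#'
#' @param object A [oat_sweep()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gp_sweep
#' @export
autoplot.gp_sweep <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$value, y = .data$NE_peak)) +
    geom_line() +
    geom_point() +
    labs(x = attr(object, "param"), y = "peak NE (persons)",
         title = "One-at-a-time sensitivity of the polarization risk")
}
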