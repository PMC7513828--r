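# Diagnostic figures: phase plane, lineage dynamics, survival curves.

#' Phase-plane portrait of the two-cluster system
#'
#' Nullclines of the two cluster equations with the equilibria overlaid
#' (filled circles: stable; open: unstable/saddle). The mirror symmetry
#' across the diagonal reflects the interchangeability of the two clusters.
#'
#' @param p A [circuit_params()] object.
#' @param n_grid Grid resolution for the nullclines.
#' @return A ggplot object.
#' @export
plot_phase_plane <- function(p = circuit_params(), n_grid = 201) {
  nc <- nullclines(p, n_grid = n_grid)
  eq <- find_equilibria(p)
  ggplot2::ggplot(nc, ggplot2::aes(x = .data$xa, y = .data$xb)) +
    ggplot2::geom_path(ggplot2::aes(colour = .data$component,
                                    group = interaction(.data$component,
                                                        .data$branch))) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3,
                         colour = "grey60") +
    ggplot2::geom_point(data = eq,
                        ggplot2::aes(shape = .data$stability == "stable"),
                        size = 3, show.legend = FALSE) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1)) +
    ggplot2::scale_colour_manual(
      values = c(xa = "firebrick", xb = "steelblue"),
      labels = c(xa = "dx_a/dt = 0", xb = "dx_b/dt = 0")) +
    ggplot2::labs(x = "NANOG in cluster a", y = "NANOG in cluster b",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

lineage_cols <- c(EPI = "#c0392b", PrE = "#2980b9", DP = "#8e44ad",
                  ESC = "#f1c40f")

#' Lineage dynamics of a simulation trajectory
#'
#' Fractional lineage sizes over time (epiblast pooled with ESCs where
#' present), with the absolute live ICM size on a secondary axis.
#'
#' @param object An `icm_trajectory` (from [run_wildtype()] and friends).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot icm_trajectory
#' @export
autoplot.icm_trajectory <- function(object, ...) {
  tb <- tibble::as_tibble(object)
  long <- tidyr::pivot_longer(
    tb, c("frac_epi", "frac_pre", "frac_dp"),
    names_to = "lineage", values_to = "fraction") |>
    dplyr::mutate(lineage = dplyr::recode(.data$lineage, frac_epi = "EPI",
                                          frac_pre = "PrE", frac_dp = "DP"))
  scale_n <- max(tb$n_live)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fraction,
                                    colour = .data$lineage)) +
    ggplot2::geom_line(data = tb,
                       ggplot2::aes(y = .data$n_live / scale_n),
                       colour = "grey40", linetype = 2) +
    ggplot2::scale_colour_manual(values = lineage_cols) +
    ggplot2::scale_y_continuous(
      "fraction of ICM",
      sec.axis = ggplot2::sec_axis(~ . * scale_n, name = "live ICM cells")) +
    ggplot2::labs(x = "time (h)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier survival curves
#'
#' @param object An `icm_survival` object (from [survival_curve()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot icm_survival
#' @export
autoplot.icm_survival <- function(object, ...) {
  curve <- attr(object, "curve")
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$time, y = .data$surv,
                                      colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 3) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (h)", y = "survival", colour = NULL) +
    ggplot2::theme_minimal()
}
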