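#' Plot switching functions
#'
#' Curves of the scale factor S(r) for the requested schemes on a common
#' cutoff.
#'
#' @param r_off cutoff (angstrom).
#' @param schemes schemes to draw.
#' @param r_on inner radius for Switch.
#' @param n grid resolution.
#' @return a ggplot.
#' @export
plot_switching <- function(r_off = 10, schemes = c("step", "shift", "switch",
                                                   "lrec"),
                           r_on = NULL, n = 400) {
  r <- seq(0, 1.1 * r_off, length.out = n)
  df <- purrr::map_dfr(schemes, function(s) {
    tibble::tibble(scheme = s, r = r,
                   S = switch_value(r, s, r_off, r_on))
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$r, .data$S,
                                   colour = .data$scheme)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = r_off, linetype = 3) +
    ggplot2::labs(x = "distance to closest QM atom (angstrom)",
                  y = "S(r)", colour = "scheme") +
    ggplot2::theme_minimal()
}

#' Plot a convergence scan
#'
#' RMSD against cutoff distance on a log scale, one panel per quantity,
#' coloured by switching scheme and shaped by model -- the standard way to
#' read off which scheme reaches a target accuracy at which cutoff.
#'
#' @param object a [convergence_scan()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.qmm_scan <- function(object, ...) {
  df <- tidy(object) |> dplyr::filter(.data$rmsd > 0)
  ggplot2::ggplot(df, ggplot2::aes(.data$r_off, .data$rmsd,
                                   colour = .data$switching,
                                   shape = .data$model,
                                   group = interaction(.data$model,
                                                       .data$switching))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "cutoff r_off (angstrom)", y = "RMSD vs reference") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot atom-site potential diagnostics
#'
#' @param diag a [site_potential_diagnostics()] result.
#' @return a ggplot comparing scaled near-field and full-environment site
#'   potentials per atom.
#' @export
plot_site_potentials <- function(diag) {
  df <- diag |>
    dplyr::select(dplyr::all_of(c("atom", "element", "phi_scaled",
                                  "phi_full"))) |>
    tidyr::pivot_longer(c("phi_scaled", "phi_full"),
                        names_to = "environment", values_to = "phi") |>
    dplyr::mutate(environment = dplyr::recode(
      .data$environment, phi_scaled = "scaled near field",
      phi_full = "full environment"))
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$atom), .data$phi,
                                   fill = .data$environment)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "QM atom", y = "site potential (a.u.)") +
    ggplot2::theme_minimal()
}
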