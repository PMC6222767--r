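#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an ESP fit
#'
#' One row per expansion site with the fitted charge and, at order 1, the
#' Cartesian dipole components and the dipole norm.
#'
#' @param x an [fit_esp_multipoles()] result.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.esp_fit <- function(x, ...) {
  out <- tibble::as_tibble(x$multipoles)
  if (attr(x$multipoles, "order") >= 1L) {
    out$mu_norm <- sqrt(out$mux^2 + out$muy^2 + out$muz^2)
  }
  out
}

#' @rdname tidy.esp_fit
#' @export
glance.esp_fit <- function(x, ...) {
  tibble::tibble(
    order = attr(x$multipoles, "order"),
    n_sites = nrow(x$multipoles),
    n_points = nrow(x$operator$K),
    residual = x$residual,
    rank = x$rank,
    n_dropped = x$n_dropped,
    total_charge = sum(x$multipoles$q))
}

#' Tidy a convergence scan
#'
#' Pivots the per-cell RMSD columns into long form (`quantity`, `rmsd`)
#' for plotting and filtering.
#'
#' @param x a [convergence_scan()] result.
#' @param ... unused.
#' @return a tibble with columns `model`, `switching`, `r_off`,
#'   `quantity`, `rmsd`.
#' @export
tidy.qmm_scan <- function(x, ...) {
  tibble::as_tibble(x) |>
    tidyr::pivot_longer(
      dplyr::any_of(c("e_rmsd", "pol_rmsd", "mulliken_rmsd", "esp_rmsd",
                      "exc_rmsd")),
      names_to = "quantity", values_to = "rmsd") |>
    dplyr::filter(!is.na(.data$rmsd)) |>
    dplyr::mutate(quantity = dplyr::recode(
      .data$quantity,
      e_rmsd = "electrostatic energy (kcal/mol)",
      pol_rmsd = "polarization energy (kcal/mol)",
      mulliken_rmsd = "Mulliken charges (e)",
      esp_rmsd = "ESP charges (e)",
      exc_rmsd = "excitation energy (eV)"))
}

#' @rdname tidy.qmm_scan
#' @export
glance.qmm_scan <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x),
    n_models = length(unique(x$model)),
    n_switchings = length(unique(x$switching)),
    r_off_min = min(x$r_off), r_off_max = max(x$r_off),
    n_failed = sum(x$n_failed))
}
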