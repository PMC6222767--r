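#' Per-element parameters used across the package
#'
#' Covers the elements that occur in typical biomolecular QM regions and as
#' counter-ions. Columns:
#' \describe{
#'   \item{element}{symbol}
#'   \item{Z}{nuclear charge (e)}
#'   \item{r_vdw}{van der Waals radius (angstrom; Bondi, with Mantina values
#'     for the metals), used to build ESP fitting surfaces}
#'   \item{r_cov}{covalent radius (angstrom; Cordero), used for bond
#'     perception in the surrogate density}
#'   \item{hardness}{atomic self-Coulomb (idempotential, hartree/e^2;
#'     Rappe-Goddard charge-equilibration values), the diagonal of the
#'     charge-flow response matrix in the surrogate backend}
#'   \item{alpha}{dipole polarizability (bohr^3); metals carry cation values
#'     since they occur here as counter-ions}
#' }
#'
#' @return A tibble with one row per supported element.
#' @export
element_table <- function() {
  ev <- 1 / 27.211386245988
  a3 <- (1 / 0.529177210903)^3 # angstrom^3 -> bohr^3
  tibble::tribble(
    ~element, ~Z, ~r_vdw, ~r_cov, ~hardness,     ~alpha,
    "H",      1,  1.20,   0.31,   13.890 * ev,  0.387 * a3,
    "B",      5,  1.92,   0.84,    8.591 * ev,  1.620 * a3,
    "C",      6,  1.70,   0.76,   10.126 * ev,  1.405 * a3,
    "N",      7,  1.55,   0.71,   11.760 * ev,  0.971 * a3,
    "O",      8,  1.52,   0.66,   13.364 * ev,  0.637 * a3,
    "F",      9,  1.47,   0.57,   15.957 * ev,  0.296 * a3,
    "Na",     11, 2.27,   1.66,    4.592 * ev,  0.180 * a3,
    "Mg",     12, 1.73,   1.41,    7.386 * ev,  0.094 * a3,
    "P",      15, 1.80,   1.07,    8.000 * ev,  1.538 * a3,
    "S",      16, 1.80,   1.05,    8.965 * ev,  2.900 * a3,
    "Cl",     17, 1.75,   1.02,    9.892 * ev,  2.315 * a3,
    "K",      19, 2.75,   2.03,    3.840 * ev,  0.830 * a3,
    "Ca",     20, 2.31,   1.76,    5.700 * ev,  0.470 * a3,
    "Br",     35, 1.85,   1.20,    8.850 * ev,  3.013 * a3,
    "I",      53, 1.98,   1.39,    7.524 * ev,  5.415 * a3
  )
}

.element_lookup <- function(elements, column, context = "element") {
  tab <- element_table()
  idx <- match(elements, tab$element)
  if (anyNA(idx)) {
    bad <- unique(elements[is.na(idx)])
    rlang::abort(
      paste0("unknown ", context, " symbol(s): ", paste(bad, collapse = ", ")),
      class = "qmmbed_validation_error"
    )
  }
  tab[[column]][idx]
}
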