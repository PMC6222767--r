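#' Physical constants and unit conversion
#'
#' All internal arithmetic in qmmbed is carried out in Hartree atomic units;
#' user-facing lengths are in angstrom and user-facing energies in kcal/mol.
#' The conversion factors are defined here and nowhere else.
#'
#' @format A named list with elements
#' \describe{
#'   \item{bohr_per_angstrom}{1 / 0.529177210903}
#'   \item{angstrom_per_bohr}{CODATA 2018 Bohr radius in angstrom}
#'   \item{kcalmol_per_hartree}{627.509474}
#'   \item{ev_per_hartree}{27.211386245988}
#' }
#' @export
qmm_constants <- list(
  angstrom_per_bohr   = 0.529177210903,
  bohr_per_angstrom   = 1 / 0.529177210903,
  kcalmol_per_hartree = 627.509474,
  ev_per_hartree      = 27.211386245988
)

# unit tag -> factor taking the tagged quantity INTO atomic units
.unit_to_au <- c(
  "angstrom" = 1 / 0.529177210903,
  "bohr"     = 1,
  "kcal/mol" = 1 / 627.509474,
  "hartree"  = 1,
  "ev"       = 1 / 27.211386245988,
  "e"        = 1
)

#' Convert quantities to and from Hartree atomic units
#'
#' Recognised unit tags: `"angstrom"`, `"bohr"` (length), `"kcal/mol"`,
#' `"hartree"`, `"ev"` (energy), `"e"` (charge). Conversions are a single
#' multiplication and are invertible to better than 1e-12 relative.
#'
#' @param x numeric vector.
#' @param from,to unit tag of `x` / of the result.
#' @return numeric vector in atomic units (`to_atomic_units`) or in `to`
#'   (`from_atomic_units`).
#' @examples
#' to_atomic_units(0.529177210903, "angstrom") # 1 bohr
#' from_atomic_units(1, "kcal/mol")            # 627.509474
#' @export
to_atomic_units <- function(x, from) {
  from <- .check_unit(from)
  x * .unit_to_au[[from]]
}

#' @rdname to_atomic_units
#' @export
from_atomic_units <- function(x, to) {
  to <- .check_unit(to)
  x / .unit_to_au[[to]]
}

.check_unit <- function(u) {
  if (!is.character(u) || length(u) != 1L) {
    rlang::abort("unit tag must be a single string", class = "qmmbed_unit_error")
  }
  u <- tolower(u)
  if (!u %in% names(.unit_to_au)) {
    rlang::abort(
      paste0("unknown unit tag '", u, "' (known: ",
             paste(names(.unit_to_au), collapse = ", "), ")"),
      class = "qmmbed_unit_error"
    )
  }
  u
}
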