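# Backend contract: any SCF engine driving the embedding models must provide
# these generics. Energies at this level are in hartree; coordinates passed
# across the boundary are in angstrom like everywhere else in the user API.

#' Capabilities advertised by a backend
#'
#' @param backend a backend object (see [surrogate_backend()]).
#' @return named logical list with entries `scf`, `esp_on_points`,
#'   `density_charge_interaction`, `tddft`.
#' @export
backend_capabilities <- function(backend) UseMethod("backend_capabilities")

#' Converge the backend's self-consistent state under an embedding operator
#'
#' Runs the backend's self-consistency procedure for the QM region in the
#' external potential described by `operator`, optionally starting from a
#' previously converged state. Both the first-cycle energy (the initial
#' state evaluated under the operator) and the converged energy are
#' returned; their difference is the polarization energy.
#'
#' @param backend a backend object.
#' @param qm a [qm_region()].
#' @param operator an embedding operator from [build_embedding_operator()],
#'   or `NULL` for a gas-phase calculation.
#' @param initial a density handle to start from, or `NULL` for the
#'   backend's default (gas-phase) guess.
#' @return list with `density` (a density handle), `e_first` and `e_conv`
#'   (hartree, relative to the backend's gas-phase ground state).
#' @export
converged_scf <- function(backend, qm, operator = NULL, initial = NULL) {
  UseMethod("converged_scf")
}

#' Electrostatic potential of a density at arbitrary points
#'
#' Nuclear plus electronic contribution, in atomic units.
#'
#' @param density a density handle.
#' @param qm the owning [qm_region()].
#' @param points n x 3 matrix of positions (angstrom) or an `esp_grid`.
#' @return numeric vector of potentials (a.u.).
#' @export
esp_on_points <- function(density, qm, points) UseMethod("esp_on_points")

#' Interaction energy between a density and external point charges
#'
#' The density-embedding energy `sum_A Z_A phi(r_A) - integral rho phi`,
#' evaluated exactly by the backend. Must agree with
#' `sum_B q_B * esp_on_points(density, r_B)`.
#'
#' @param density a density handle.
#' @param qm the owning [qm_region()].
#' @param charges an [mm_charges()] subset (column `q_eff` honoured).
#' @return energy in hartree.
#' @export
density_charge_interaction <- function(density, qm, charges) {
  UseMethod("density_charge_interaction")
}

#' Vertical excitation energies in an embedding potential
#'
#' Lowest singlet vertical excitation energies with the embedding operator
#' included in the ground-state Hamiltonian only; the embedding charges are
#' static, so no response-kernel contribution arises.
#'
#' @param density a converged density handle.
#' @param qm the owning [qm_region()].
#' @param operator embedding operator or `NULL` (gas phase).
#' @param n_states number of states.
#' @return numeric vector of excitation energies (eV).
#' @export
excitation_energies <- function(density, qm, operator = NULL, n_states = 1L) {
  UseMethod("excitation_energies")
}

# density-handle accessors used by the Mulliken analysis ----------------------

#' Low-level density-handle accessors
#'
#' A density handle exposes its one-particle density matrix, the overlap and
#' first-moment integrals over its basis, the basis-to-atom ownership map,
#' and the electron count. [mulliken_multipoles()] is written against these
#' accessors only, so any backend that provides them gets population
#' analysis for free.
#'
#' @param density a density handle.
#' @return `density_matrix()`, `overlap_matrix()`: square matrices;
#'   `moment_matrices()`: list of three matrices (x, y, z first moments,
#'   bohr); `basis_atoms()`: integer owner per basis function;
#'   `electron_count()`: scalar.
#' @name density-accessors
NULL

#' @rdname density-accessors
#' @export
density_matrix <- function(density) UseMethod("density_matrix")

#' @rdname density-accessors
#' @export
overlap_matrix <- function(density) UseMethod("overlap_matrix")

#' @rdname density-accessors
#' @export
moment_matrices <- function(density) UseMethod("moment_matrices")

#' @rdname density-accessors
#' @export
basis_atoms <- function(density) UseMethod("basis_atoms")

#' @rdname density-accessors
#' @export
electron_count <- function(density) UseMethod("electron_count")

#' Select a backend by name
#'
#' @param name backend identifier; `"surrogate"` is the classical
#'   polarizable backend shipped with the package.
#' @param ... passed to the backend constructor.
#' @return a backend object.
#' @export
get_backend <- function(name = "surrogate", ...) {
  switch(tolower(name),
    surrogate = surrogate_backend(...),
    rlang::abort(paste0("unknown backend '", name, "'"),
                 class = "qmmbed_validation_error"))
}
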