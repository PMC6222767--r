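.embedding_models <- c("reference", "truncation", "truncation_mmlc",
                       "mulc", "mulcd", "espc", "espcd", "mechanical")

# long-range truncation order implied by the model name
.model_order <- function(model) {
  switch(model, mulc = 0L, espc = 0L, mulcd = 1L, espcd = 1L, 1L)
}

.check_model <- function(model) {
  model <- tolower(model)
  if (!model %in% .embedding_models) {
    rlang::abort(paste0("unknown embedding model '", model, "'"),
                 class = "qmmbed_validation_error")
  }
  model
}

#' Mechanical-embedding QM/MM electrostatic energy
#'
#' Fixed pre-computed reference charges on the QM atoms interact classically
#' with the MM point charges: `sum_A sum_B q_A^ref q_B / |r_A - r_B|`.
#'
#' @param qm a [qm_region()] with `q_ref`.
#' @param mm an [mm_charges()] subset (column `q_eff` honoured).
#' @return energy in kcal/mol.
#' @examples
#' qm <- qm_region("H", matrix(c(0, 0, 0), 1), q_ref = 1)
#' mm <- mm_charges(matrix(c(0.529177210903, 0, 0), 1), q = -1, group = 1)
#' mechanical_energy(qm, mm) # -627.509474
#' @export
mechanical_energy <- function(qm, mm) {
  qa <- .qm_ff_charges(qm)
  if (nrow(mm) == 0L) return(0)
  qb <- if ("q_eff" %in% names(mm)) mm$q_eff else mm$q
  Tm <- .tensor_matrix(.coords_bohr(qm), .coords_bohr(mm), order = 0L)
  drop(t(qa) %*% Tm %*% qb) * qmm_constants$kcalmol_per_hartree
}

#' Density-embedding QM/MM electrostatic energy
#'
#' Exact interaction of the QM density (nuclei plus electron density) with a
#' set of MM point charges, delegated to the backend's density-charge
#' interaction.
#'
#' @param density a density handle.
#' @param qm the owning [qm_region()].
#' @param mm an [mm_charges()] subset (column `q_eff` honoured).
#' @return energy in kcal/mol.
#' @export
density_embedding_energy <- function(density, qm, mm) {
  density_charge_interaction(density, qm, mm) *
    qmm_constants$kcalmol_per_hartree
}

#' Multipolar QM/MM electrostatic energy
#'
#' Contraction of per-site generalized moments with the local Taylor
#' expansion of the MM potential: `sum_A sum_m M_A^m F_A^m`, i.e. charge
#' times potential plus (at order 1) dipole times field.
#'
#' @param M a `multipole_set`.
#' @param F a [local_field()] evaluated at the same sites, with order at
#'   least that of `M`.
#' @return energy in kcal/mol.
#' @export
multipolar_energy <- function(M, F) {
  if (nrow(M) != nrow(F)) {
    rlang::abort("multipole set and local field have different site counts",
                 class = "qmmbed_validation_error")
  }
  order <- attr(M, "order")
  if (attr(F, "order") < order) {
    rlang::abort("local field order is lower than the multipole order",
                 class = "qmmbed_validation_error")
  }
  e <- sum(M$q * F$phi)
  if (order >= 1L) {
    e <- e + sum(M$mux * F$ex + M$muy * F$ey + M$muz * F$ez)
  }
  e * qmm_constants$kcalmol_per_hartree
}

#' MM-level long-range correction (MMLC)
#'
#' Far-field QM/MM electrostatics evaluated classically with force-field
#' charges on the QM atoms, added on top of a truncated calculation. It
#' corrects the energy only; the QM electronic structure is untouched.
#'
#' @param qm a [qm_region()] with `q_ref`.
#' @param mm_far the far-field [mm_charges()] subset.
#' @return energy in kcal/mol.
#' @export
mmlc_correction <- function(qm, mm_far) mechanical_energy(qm, mm_far)

# long-range charge set of a split: scaled complements of near charges plus
# full far charges, as a tibble with q_eff
.long_range_set <- function(split) {
  out <- tibble::as_tibble(split)
  out$q_eff <- ifelse(out$near, out$q_II, out$q)
  out[abs(out$q_eff) > 0, c("x", "y", "z", "q", "q_eff")]
}

.short_range_set <- function(split) {
  out <- tibble::as_tibble(split)
  out <- out[out$near & abs(out$q_I) > 0, , drop = FALSE]
  out$q_eff <- out$q_I
  out[, c("x", "y", "z", "q", "q_eff")]
}

#' Hybrid short/long-range QM/MM electrostatic energy
#'
#' The near field (scaled charges `q_I`) interacts with the explicit QM
#' density; the long-range set (complements `q_II` plus all far charges)
#' interacts with a multipolar representation of the same density --
#' Mulliken or ESP charges (order 0) or charges and dipoles (order 1) -- or,
#' for the truncation models, is dropped or handled at the MM level.
#'
#' @param density a density handle (the density whose energy is evaluated,
#'   typically the reference converged density).
#' @param qm the [qm_region()].
#' @param mm the full [mm_charges()] environment.
#' @param model one of `"reference"`, `"truncation"`, `"truncation_mmlc"`,
#'   `"mulc"`, `"mulcd"`, `"espc"`, `"espcd"`.
#' @param scheme,r_off,r_on switching specification (see [switch_value()]).
#' @param mode cutoff mode; defaults to `"group"` for Step and `"atom"` for
#'   the smooth schemes.
#' @param grid optional pre-built [build_esp_grid()] for the ESP models.
#' @return one-row tibble of class `energy_report` with columns `model`,
#'   `switching`, `r_off`, `mode`, `short_range`, `long_range`, `mmlc`,
#'   `total` (kcal/mol); `total = short_range + long_range + mmlc`.
#' @export
hybrid_energy <- function(density, qm, mm, model = "espcd", scheme = "lrec",
                          r_off = 10, r_on = NULL, mode = NULL, grid = NULL) {
  model <- .check_model(model)
  if (model == "mechanical") {
    rlang::abort("use mechanical_energy() for the mechanical model",
                 class = "qmmbed_validation_error")
  }
  scheme <- tolower(scheme)
  if (is.null(mode)) mode <- if (scheme == "step") "group" else "atom"
  if (model == "reference") {
    e_short <- density_embedding_energy(density, qm, mm)
    return(.energy_report(model, scheme, r_off, mode, e_short, 0, 0))
  }
  part <- partition_charges(mm, qm, r_off, mode)
  split <- split_charges(part, scheme, r_on)
  short_set <- .short_range_set(split)
  long_set <- .long_range_set(split)
  e_short <- density_embedding_energy(density, qm, short_set)
  e_long <- 0; e_mmlc <- 0
  if (nrow(long_set)) {
    order <- .model_order(model)
    if (model %in% c("mulc", "mulcd")) {
      M <- mulliken_multipoles(density, qm, order)
      e_long <- multipolar_energy(M, local_field(long_set, qm, order))
    } else if (model %in% c("espc", "espcd")) {
      if (is.null(grid)) grid <- build_esp_grid(qm)
      phi <- esp_on_points(density, qm, grid)
      fit <- fit_esp_multipoles(grid, phi, qm, order)
      e_long <- multipolar_energy(fit$multipoles,
                                  local_field(long_set, qm, order))
    } else if (model == "truncation_mmlc") {
      e_mmlc <- mmlc_correction(qm, long_set)
    } # truncation: long-range set dropped
  }
  .energy_report(model, scheme, r_off, mode, e_short, e_long, e_mmlc)
}

.energy_report <- function(model, scheme, r_off, mode, e_short, e_long,
                           e_mmlc) {
  out <- tibble::tibble(
    model = model, switching = scheme, r_off = r_off, mode = mode,
    short_range = e_short, long_range = e_long, mmlc = e_mmlc,
    total = e_short + e_long + e_mmlc)
  class(out) <- c("energy_report", class(out))
  out
}

#' Build the embedding operator handed to the SCF backend
#'
#' Realizes each model's embedding potential for the one-electron
#' Hamiltonian: scaled near-field charges always enter as external point
#' charges; for the ESP models the long-range set is projected onto the ESP
#' grid and enters as static grid point charges (density-independent, hence
#' variationally exact); for the Mulliken models the long-range set enters
#' through a constant one-electron site-field term (the energy is linear in
#' the density matrix, so the matrix is built once per geometry); the
#' truncation models carry no far-field term.
#'
#' @param model embedding model name (`"reference"` uses all charges
#'   unscaled).
#' @param split a [split_charges()] result over the full MM environment.
#' @param qm the [qm_region()].
#' @param grid [build_esp_grid()] result; required for the ESP models.
#' @param op optional [esp_operator()] to reuse for the projection.
#' @return list of class `embedding_operator` with elements `model`,
#'   `charges` (tibble `x`, `y`, `z`, `q`), optional `site_field` (per-site
#'   `phi`, `ex`, `ey`, `ez`, a.u.) and `nuclear_shift` (hartree).
#' @export
build_embedding_operator <- function(model, split, qm, grid = NULL,
                                     op = NULL) {
  model <- .check_model(model)
  if (model == "mechanical") {
    rlang::abort("the mechanical model has no embedding operator",
                 class = "qmmbed_validation_error")
  }
  if (model == "reference") {
    ch <- tibble::as_tibble(split)[, c("x", "y", "z", "q")]
    return(structure(list(model = model, charges = ch, site_field = NULL,
                          nuclear_shift = 0),
                     class = "embedding_operator"))
  }
  short_set <- .short_range_set(split)
  charges <- tibble::tibble(x = short_set$x, y = short_set$y,
                            z = short_set$z, q = short_set$q_eff)
  long_set <- .long_range_set(split)
  site_field <- NULL; nuclear_shift <- 0
  order <- .model_order(model)
  if (nrow(long_set)) {
    if (model %in% c("espc", "espcd")) {
      if (is.null(grid)) {
        rlang::abort("ESP models require a fitting grid",
                     class = "qmmbed_validation_error")
      }
      gq <- project_mm_to_grid(long_set, grid, qm, order, op = op)
      charges <- dplyr::bind_rows(
        charges, tibble::tibble(x = gq$x, y = gq$y, z = gq$z, q = gq$q_s))
    } else if (model %in% c("mulc", "mulcd")) {
      F <- local_field(long_set, qm, order)
      site_field <- tibble::tibble(
        phi = F$phi,
        ex = if (order >= 1L) F$ex else 0,
        ey = if (order >= 1L) F$ey else 0,
        ez = if (order >= 1L) F$ez else 0)
      nuclear_shift <- sum(qm$Z * site_field$phi)
    } # truncation models: nothing beyond the near field
  }
  structure(list(model = model, charges = charges, site_field = site_field,
                 nuclear_shift = nuclear_shift),
            class = "embedding_operator")
}

#' QM/MM polarization energy
#'
#' Energy difference between the last and first SCF cycles when the QM
#' region relaxes in a given embedding potential, starting from a reference
#' converged density: `E[converged under operator] - E[start density under
#' operator]`. Non-positive by the variational principle; its magnitude
#' measures how far the starting orbitals are from self-consistency in that
#' potential.
#'
#' @param backend an SCF backend.
#' @param qm the [qm_region()].
#' @param operator an embedding operator (or `NULL` for gas phase).
#' @param start_density density handle to start from (typically the
#'   reference-scheme converged density).
#' @return energy in kcal/mol (<= 0).
#' @export
polarization_energy <- function(backend, qm, operator, start_density) {
  scf <- converged_scf(backend, qm, operator, initial = start_density)
  (scf$e_conv - scf$e_first) * qmm_constants$kcalmol_per_hartree
}
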