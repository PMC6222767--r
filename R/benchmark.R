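#' Root-mean-square deviation
#'
#' `sqrt(mean((values - reference)^2))`; `reference` may be a scalar.
#'
#' @param values numeric vector.
#' @param reference numeric vector of the same length, or a scalar.
#' @return non-negative scalar.
#' @examples
#' rmsd(c(0, 0), c(3, 4)) # sqrt(12.5)
#' @export
rmsd <- function(values, reference) {
  if (length(reference) == 1L) reference <- rep(reference, length(values))
  if (length(values) != length(reference) || length(values) < 1L) {
    rlang::abort("values and reference must have equal lengths >= 1",
                 class = "qmmbed_validation_error")
  }
  sqrt(mean((values - reference)^2))
}

.boot_ci <- function(dev, n_boot, probs = c(0.05, 0.95)) {
  if (n_boot <= 0L || length(dev) < 2L) return(c(NA_real_, NA_real_))
  reps <- vapply(seq_len(n_boot), function(i) {
    sqrt(mean(sample(dev, replace = TRUE)^2))
  }, numeric(1))
  stats::quantile(reps, probs, names = FALSE)
}

#' Atom-site potential diagnostics
#'
#' Potentials and fields at every QM atom from (a) the scaled near-field
#' charges only and (b) the full MM environment. Around an anion the full
#' environment produces positive site potentials; a hard truncation
#' underestimates them, while smooth scaling recovers most of the
#' stabilization because solvent hydrogens (closer, positive) keep larger
#' scale factors than oxygens of the same molecule.
#'
#' @param qm a [qm_region()].
#' @param mm the full [mm_charges()].
#' @param split a [split_charges()] result for `mm`.
#' @return tibble, one row per QM atom: `phi_scaled`, `ex_scaled`, ...,
#'   `phi_full`, `ex_full`, ... (a.u.).
#' @export
site_potential_diagnostics <- function(qm, mm, split) {
  near <- .short_range_set(split)
  Fs <- local_field(near, qm, order = 1L)
  Ff <- local_field(mm, qm, order = 1L)
  tibble::tibble(
    atom = seq_len(nrow(qm)), element = qm$element,
    phi_scaled = Fs$phi, ex_scaled = Fs$ex, ey_scaled = Fs$ey,
    ez_scaled = Fs$ez,
    phi_full = Ff$phi, ex_full = Ff$ex, ey_full = Ff$ey, ez_full = Ff$ez)
}

#' Convergence scan of embedding schemes against the all-charge reference
#'
#' For every configuration the reference state is computed once: all MM
#' charges density-embedded, SCF converged, giving the reference
#' electrostatic energy, atomic charges and excitation energies. Every
#' (model, switching, cutoff) cell is then evaluated with the reference
#' density (electrostatic energy), with its own SCF started from the
#' reference density (polarization energy, relaxed charges) and with its
#' operator in the excitation calculation; deviations are aggregated over
#' configurations. Step cells use group-based cutoffs, smooth-switching
#' cells atom-based cutoffs, unless `mode` overrides.
#'
#' @param configs list of `list(qm = , mm = )` pairs (see
#'   [benchmark_configs()]); at least 2 for a meaningful RMSD.
#' @param models character vector of embedding models.
#' @param switchings character vector of switching schemes.
#' @param cutoffs numeric vector of `r_off` values (angstrom).
#' @param backend an SCF backend.
#' @param mode optional cutoff-mode override (`"atom"`/`"group"`).
#' @param n_states excitation states tracked (the lowest enters the RMSD).
#' @param n_boot bootstrap replicates for an energy-RMSD interval
#'   (0 = off).
#' @param quantities subset of `c("energy", "polarization", "charges",
#'   "excitation")` to compute.
#' @return tibble of class `qmm_scan`: one row per cell with `model`,
#'   `switching`, `r_off`, `n_configs`, `e_rmsd`, `pol_rmsd`,
#'   `mulliken_rmsd`, `esp_rmsd`, `exc_rmsd` (kcal/mol, kcal/mol, e, e,
#'   eV), a failure count `n_failed`, and optional `e_rmsd_lo`/`e_rmsd_hi`.
#' @export
convergence_scan <- function(configs, models = "espcd", switchings = "lrec",
                             cutoffs = c(0, 5, 10, 15, 20, 25, 30),
                             backend = surrogate_backend(), mode = NULL,
                             n_states = 1L, n_boot = 0L,
                             quantities = c("energy", "polarization",
                                            "charges", "excitation")) {
  if (length(configs) < 2L) {
    rlang::abort("need at least 2 configurations for an RMSD",
                 class = "qmmbed_validation_error")
  }
  models <- vapply(models, .check_model, character(1))
  do_pol <- "polarization" %in% quantities
  do_chg <- "charges" %in% quantities
  do_exc <- "excitation" %in% quantities
  need_scf <- do_pol || do_chg || do_exc
  need_grid <- do_chg || any(models %in% c("espc", "espcd"))

  refs <- lapply(configs, function(cf) {
    qm <- cf$qm; mm <- cf$mm
    op_ref <- build_embedding_operator(
      "reference", tibble::as_tibble(mm), qm)
    scf <- converged_scf(backend, qm, op_ref)
    grid <- if (need_grid) build_esp_grid(qm) else NULL
    ops <- if (need_grid) {
      list(esp_operator(grid, qm, 0L), esp_operator(grid, qm, 1L))
    }
    list(
      qm = qm, mm = mm, grid = grid, ops = ops, density = scf$density,
      e = density_embedding_energy(scf$density, qm, mm),
      mull_q = if (do_chg) mulliken_multipoles(scf$density, qm, 1L)$q,
      esp_q = if (do_chg) {
        fit_esp_multipoles(grid, esp_on_points(scf$density, qm, grid), qm,
                           1L, op = ops[[2]])$multipoles$q
      },
      exc = if (do_exc) excitation_energies(scf$density, qm, op_ref,
                                            n_states))
  })

  cells <- tidyr::expand_grid(model = models, switching = tolower(switchings),
                              r_off = cutoffs)
  rows <- purrr::pmap(cells, function(model, switching, r_off) {
    mode_c <- mode %||% if (switching == "step") "group" else "atom"
    dev_e <- dev_pol <- dev_mq <- dev_eq <- dev_exc <- numeric(0)
    n_failed <- 0L
    for (rf in refs) {
      res <- tryCatch({
        rep_ <- hybrid_energy(rf$density, rf$qm, rf$mm, model, switching,
                              r_off, mode = mode_c, grid = rf$grid)
        out <- list(de = rep_$total - rf$e)
        if (need_scf) {
          split <- split_charges(
            partition_charges(rf$mm, rf$qm, r_off, mode_c), switching)
          op_m <- build_embedding_operator(
            model, split, rf$qm, grid = rf$grid,
            op = if (!is.null(rf$ops)) rf$ops[[.model_order(model) + 1L]])
          scf_m <- converged_scf(backend, rf$qm, op_m, initial = rf$density)
          if (do_pol) {
            out$dpol <- (scf_m$e_conv - scf_m$e_first) *
              qmm_constants$kcalmol_per_hartree
          }
          if (do_chg) {
            out$dmq <- rmsd(mulliken_multipoles(scf_m$density, rf$qm, 1L)$q,
                            rf$mull_q)
            fit <- fit_esp_multipoles(
              rf$grid, esp_on_points(scf_m$density, rf$qm, rf$grid),
              rf$qm, 1L, op = rf$ops[[2]])
            out$deq <- rmsd(fit$multipoles$q, rf$esp_q)
          }
          if (do_exc) {
            exc <- excitation_energies(scf_m$density, rf$qm, op_m, n_states)
            out$dexc <- exc[1] - rf$exc[1]
          }
        }
        out
      }, error = function(e) NULL)
      if (is.null(res)) { n_failed <- n_failed + 1L; next }
      dev_e <- c(dev_e, res$de)
      if (do_pol) dev_pol <- c(dev_pol, res$dpol)
      if (do_chg) { dev_mq <- c(dev_mq, res$dmq); dev_eq <- c(dev_eq, res$deq) }
      if (do_exc) dev_exc <- c(dev_exc, res$dexc)
    }
    ci <- .boot_ci(dev_e, n_boot)
    tibble::tibble(
      model = model, switching = switching, r_off = r_off,
      n_configs = length(dev_e), n_failed = n_failed,
      e_rmsd = if (length(dev_e)) sqrt(mean(dev_e^2)) else NA_real_,
      pol_rmsd = if (do_pol && length(dev_pol)) sqrt(mean(dev_pol^2))
                 else NA_real_,
      mulliken_rmsd = if (do_chg && length(dev_mq)) mean(dev_mq)
                      else NA_real_,
      esp_rmsd = if (do_chg && length(dev_eq)) mean(dev_eq) else NA_real_,
      exc_rmsd = if (do_exc && length(dev_exc)) sqrt(mean(dev_exc^2))
                 else NA_real_,
      e_rmsd_lo = ci[1], e_rmsd_hi = ci[2])
  })
  out <- dplyr::bind_rows(rows)
  if (n_boot <= 0L) out$e_rmsd_lo <- out$e_rmsd_hi <- NULL
  class(out) <- c("qmm_scan", class(tibble::tibble()))
  out
}
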