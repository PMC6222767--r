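# ---- interaction tensors ----------------------------------------------------

# Stacked charge/dipole--charge interaction tensor in atomic units.
# sites, sources: matrices in bohr. Returns (n_sites * n_m) x n_sources with
# site-major row order (site 1: m = 0, x, y, z; site 2: ...). n_m = 1 or 4.
.tensor_matrix <- function(sites, sources, order) {
  n_m <- if (order >= 1L) 4L else 1L
  nA <- nrow(sites); nB <- nrow(sources)
  if (nB == 0L) return(matrix(0, nA * n_m, 0L))
  dx <- outer(sites[, 1], sources[, 1], "-")
  dy <- outer(sites[, 2], sources[, 2], "-")
  dz <- outer(sites[, 3], sources[, 3], "-")
  r2 <- dx^2 + dy^2 + dz^2
  if (any(r2 < 1e-20)) {
    k <- which(r2 < 1e-20, arr.ind = TRUE)[1, ]
    rlang::abort(sprintf(
      "singular interaction tensor: site %d coincides with source %d",
      k[1], k[2]), class = "qmmbed_singular_error")
  }
  rinv <- 1 / sqrt(r2)
  out <- matrix(0, nA * n_m, nB)
  out[seq(1L, by = n_m, length.out = nA), ] <- rinv
  if (order >= 1L) {
    r3inv <- rinv^3
    out[seq(2L, by = n_m, length.out = nA), ] <- dx * r3inv
    out[seq(3L, by = n_m, length.out = nA), ] <- dy * r3inv
    out[seq(4L, by = n_m, length.out = nA), ] <- dz * r3inv
  }
  out
}

#' Multipole-charge interaction tensor
#'
#' Components coupling the generalized moments (charge, Cartesian dipole) at
#' `site` to a unit point charge at `source`:
#' `T0 = 1/|r_A - r_B|` and `T1 = (r_A - r_B)/|r_A - r_B|^3`.
#' Positions and results are in atomic units (bohr).
#'
#' @param site,source numeric length-3 positions (bohr); must differ.
#' @param order 0 (charge only) or 1 (charge + dipole).
#' @return named numeric vector `c(m0, m1x, m1y, m1z)` (order 1) or `c(m0)`.
#' @examples
#' interaction_tensor(c(0, 0, 0), c(2, 0, 0), order = 1)
#' @export
interaction_tensor <- function(site, source, order = 1L) {
  v <- .tensor_matrix(rbind(site), rbind(source), order)[, 1]
  names(v) <- if (order >= 1L) c("m0", "m1x", "m1y", "m1z") else "m0"
  v
}

#' Local Taylor expansion of the MM potential at expansion sites
#'
#' Electrostatic potential and field generated by a set of point charges at
#' each QM expansion site: `phi_A = sum_B q_B / r_AB` and the corresponding
#' tensor components for the dipole channel. Linear in the charges.
#'
#' @param charges an [mm_charges()] (coordinates in angstrom, charges in e);
#'   a column `q_eff` overrides `q` when present (used for split charges).
#' @param sites a [qm_region()] or an n x 3 matrix of positions in angstrom.
#' @param order 0 or 1.
#' @return tibble of class `local_field`, one row per site: `phi` plus, at
#'   order 1, `ex`, `ey`, `ez` (atomic units).
#' @export
local_field <- function(charges, sites, order = 1L) {
  S <- if (is.matrix(sites)) sites * qmm_constants$bohr_per_angstrom
       else .coords_bohr(sites)
  q <- if ("q_eff" %in% names(charges)) charges$q_eff else charges$q
  n_m <- if (order >= 1L) 4L else 1L
  if (nrow(charges) == 0L) {
    F <- matrix(0, nrow(S) * n_m, 1)
  } else {
    Tm <- tryCatch(
      .tensor_matrix(S, .coords_bohr(charges), order),
      qmmbed_singular_error = function(e) {
        rlang::abort(paste0("MM charge coincides with an expansion site: ",
                            conditionMessage(e)),
                     class = "qmmbed_singular_error")
      })
    F <- Tm %*% q
  }
  M <- matrix(F, ncol = n_m, byrow = TRUE)
  out <- tibble::tibble(phi = M[, 1])
  if (order >= 1L) {
    out$ex <- M[, 2]; out$ey <- M[, 3]; out$ez <- M[, 4]
  }
  attr(out, "order") <- as.integer(order)
  class(out) <- c("local_field", class(out))
  out
}

# local_field tibble -> stacked site-major vector matching .tensor_matrix rows
.field_vector <- function(F) {
  order <- attr(F, "order")
  if (order >= 1L) as.vector(t(cbind(F$phi, F$ex, F$ey, F$ez)))
  else F$phi
}

.multipole_vector <- function(M) {
  if (attr(M, "order") >= 1L) as.vector(t(cbind(M$q, M$mux, M$muy, M$muz)))
  else M$q
}

.new_multipole_set <- function(qm, q, mu = NULL, order, method) {
  out <- tibble::tibble(
    site = seq_len(nrow(qm)), element = qm$element,
    x = qm$x, y = qm$y, z = qm$z, q = as.numeric(q)
  )
  if (order >= 1L) {
    if (is.null(mu)) mu <- matrix(0, nrow(qm), 3)
    out$mux <- mu[, 1]; out$muy <- mu[, 2]; out$muz <- mu[, 3]
  }
  attr(out, "order") <- as.integer(order)
  attr(out, "method") <- method
  class(out) <- c("multipole_set", class(out))
  out
}

#' Reference force-field charges as a multipole set
#'
#' Wraps the fixed `q_ref` charges of a QM region as an order-0 multipole set
#' (the representation used by mechanical embedding).
#'
#' @param qm a [qm_region()] with `q_ref`.
#' @return a `multipole_set` of method `"reference_ff"`.
#' @export
reference_multipoles <- function(qm) {
  .new_multipole_set(qm, .qm_ff_charges(qm), order = 0L,
                     method = "reference_ff")
}

# ---- Mulliken ---------------------------------------------------------------

#' Mulliken charges and atomic dipoles of a density
#'
#' Partitions the one-particle density matrix by basis-function ownership:
#' atom A receives its diagonal block plus all cross terms with one index on
#' A (evaluated with the symmetrized density matrix). The charge is
#' `q_A = Z_A - N_A` with `N_A` the gross population; the atomic dipole is
#' the first moment of the (positive) atomic electron density about the
#' atom, the convention under which the multipolar energy with the
#' charge-dipole interaction tensor reproduces the exact density-charge
#' energy in the far field.
#'
#' @param density a density handle from a backend (see [surrogate_backend()]);
#'   must expose a density matrix, overlap and moment integrals.
#' @param qm the owning [qm_region()].
#' @param order 0 or 1.
#' @return a `multipole_set` of method `"mulliken"` (charges in e, dipoles in
#'   e bohr).
#' @export
mulliken_multipoles <- function(density, qm, order = 1L) {
  if (order > 1L) {
    rlang::abort("moments beyond dipoles are not supported",
                 class = "qmmbed_validation_error")
  }
  P <- density_matrix(density)
  S <- overlap_matrix(density)
  owner <- basis_atoms(density)
  Ps <- (P + t(P)) / 2
  G <- Ps * S # gross population contributions
  pop_by_basis <- rowSums(G)
  N_A <- vapply(seq_len(nrow(qm)), function(a) sum(pop_by_basis[owner == a]),
                numeric(1))
  q <- qm$Z - N_A
  mu <- NULL
  if (order >= 1L) {
    D <- moment_matrices(density) # list of X, Y, Z first-moment integrals
    sites <- .coords_bohr(qm)
    mu <- matrix(0, nrow(qm), 3)
    for (k in 1:3) {
      rowsum_k <- rowSums(Ps * D[[k]])
      for (a in seq_len(nrow(qm))) {
        sel <- owner == a
        mu[a, k] <- sum(rowsum_k[sel]) - sites[a, k] * N_A[a]
      }
    }
  }
  .new_multipole_set(qm, q, mu, order, "mulliken")
}

# ---- ESP grid and fit -------------------------------------------------------

#' Build a layered van der Waals surface grid for ESP fitting
#'
#' Merz-Kollman-style construction: for every QM atom, spherical shells at
#' `shells` times its van der Waals radius, discretized by a deterministic
#' Fibonacci-sphere placement at roughly `density` points per square
#' angstrom; points falling inside any other atom's shell at the same scale
#' are pruned. The default four layers at 1.4-2.0 x Bondi radii are the
#' standard ESP grid.
#'
#' @param qm a [qm_region()].
#' @param shells numeric vector of vdW scale factors.
#' @param density surface point density (points per square angstrom).
#' @return tibble of class `esp_grid` with columns `x`, `y`, `z` (angstrom),
#'   `atom`, `shell`.
#' @export
build_esp_grid <- function(qm, shells = c(1.4, 1.6, 1.8, 2.0), density = 1.0) {
  rv <- .element_lookup(qm$element, "r_vdw")
  centers <- .coords_ang(qm)
  pieces <- list()
  for (s in shells) {
    radii <- s * rv
    for (a in seq_len(nrow(qm))) {
      r <- radii[a]
      n <- max(1L, as.integer(round(4 * pi * r^2 * density)))
      pts <- .fibonacci_sphere(n) * r
      pts <- sweep(pts, 2, centers[a, ], "+")
      # prune points inside another atom's same-scale shell
      keep <- rep(TRUE, nrow(pts))
      for (b in seq_len(nrow(qm))[-a]) {
        d2 <- rowSums(sweep(pts, 2, centers[b, ], "-")^2)
        keep <- keep & d2 >= (radii[b] * (1 - 1e-9))^2
      }
      if (any(keep)) {
        pieces[[length(pieces) + 1L]] <- tibble::tibble(
          x = pts[keep, 1], y = pts[keep, 2], z = pts[keep, 3],
          atom = a, shell = s)
      }
    }
  }
  out <- dplyr::bind_rows(pieces)
  class(out) <- c("esp_grid", class(out))
  out
}

# deterministic Fibonacci sphere: n unit vectors
.fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- 2 * pi * i * (sqrt(5) - 1) / 2
  rho <- sqrt(pmax(1 - z^2, 0))
  cbind(rho * cos(phi), rho * sin(phi), z)
}

#' ESP coupling operator between QM sites and grid points
#'
#' Builds the coupling tensor `K[s, Am]` (same closed form as the
#' multipole-charge interaction tensor, with grid points as the sources) and
#' its minimum-norm pseudo-inverse via singular value decomposition.
#' Singular values below `svd_tol` times the largest are discarded.
#'
#' @param grid a [build_esp_grid()] result.
#' @param qm the [qm_region()].
#' @param order 0 or 1.
#' @param svd_tol relative singular-value cutoff.
#' @return list of class `esp_operator` with elements `K` (points x moments),
#'   `pinv` (moments x points), `order`, `n_dropped`, `rank`.
#' @export
esp_operator <- function(grid, qm, order = 1L, svd_tol = 1e-6) {
  n_m <- if (order >= 1L) 4L else 1L
  n_unknowns <- nrow(qm) * n_m
  if (nrow(grid) < n_unknowns) {
    rlang::abort(sprintf(
      "underdetermined ESP fit: %d grid points < %d unknowns",
      nrow(grid), n_unknowns), class = "qmmbed_validation_error")
  }
  K <- t(.tensor_matrix(.coords_bohr(qm), .coords_bohr(grid), order))
  sv <- svd(K)
  keep <- sv$d > svd_tol * sv$d[1]
  pinv <- sv$v[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
  structure(
    list(K = K, pinv = pinv, order = as.integer(order),
         n_dropped = sum(!keep), rank = sum(keep)),
    class = "esp_operator")
}

#' Fit ESP charges and dipoles to grid potentials
#'
#' Minimum-norm least-squares solution of `K M = phi` via the SVD
#' pseudo-inverse: atomic charges (order 0) or charges plus Cartesian
#' dipoles (order 1) that best reproduce the electrostatic potential on the
#' fitting grid. Optionally the total charge can be constrained to a given
#' value with a Lagrange multiplier (off by default; the plain
#' pseudo-inverse is the standard route).
#'
#' @param grid a [build_esp_grid()] result.
#' @param phi numeric vector of target potentials at the grid points (a.u.).
#' @param qm the [qm_region()].
#' @param order 0 or 1.
#' @param constrain_total optional total charge (e) to enforce.
#' @param op an [esp_operator()] to reuse; built on the fly if `NULL`.
#' @return list of class `esp_fit`: `multipoles` (a `multipole_set` of
#'   method `"esp"`), `residual` (RMS potential error, a.u.), `rank`,
#'   `n_dropped`, and the operator used.
#' @export
fit_esp_multipoles <- function(grid, phi, qm, order = 1L,
                               constrain_total = NULL, op = NULL) {
  if (length(phi) != nrow(grid)) {
    rlang::abort("phi must have one value per grid point",
                 class = "qmmbed_validation_error")
  }
  if (is.null(op)) op <- esp_operator(grid, qm, order)
  stopifnot(op$order == order)
  m <- drop(op$pinv %*% phi)
  if (!is.null(constrain_total)) {
    # KKT correction: shift the minimum-norm solution along the constraint
    # gradient within the normal-equation metric
    n_m <- if (order >= 1L) 4L else 1L
    cvec <- rep(0, nrow(qm) * n_m)
    cvec[seq(1L, by = n_m, length.out = nrow(qm))] <- 1
    KtK_inv_c <- drop(op$pinv %*% (t(op$pinv) %*% cvec))
    lambda <- (sum(cvec * m) - constrain_total) / sum(cvec * KtK_inv_c)
    m <- m - lambda * KtK_inv_c
  }
  n_m <- if (order >= 1L) 4L else 1L
  Mm <- matrix(m, ncol = n_m, byrow = TRUE)
  ms <- .new_multipole_set(
    qm, q = Mm[, 1],
    mu = if (order >= 1L) Mm[, 2:4, drop = FALSE] else NULL,
    order = order, method = "esp")
  resid <- drop(op$K %*% m) - phi
  structure(
    list(multipoles = ms, residual = sqrt(mean(resid^2)), rank = op$rank,
         n_dropped = op$n_dropped, operator = op),
    class = "esp_fit")
}

#' Project MM charges onto the ESP grid
#'
#' Converts a set of MM point charges into equivalent charges on the ESP
#' grid: `q_s = sum_Am F_Am (K^-1)_Am,s`, where `F` is the potential/field
#' of the MM charges at the QM sites. By construction the multipolar energy
#' `sum_Am M_Am F_Am` equals `sum_s q_s phi_s` for every grid potential
#' `phi_s` and its fitted multipoles, so the far field can enter an SCF as
#' static external point charges.
#'
#' @param mm_far an [mm_charges()] subset (column `q_eff` honoured).
#' @param grid the fitting grid.
#' @param qm the [qm_region()].
#' @param order 0 or 1.
#' @param op optional [esp_operator()] to reuse (must match `order`).
#' @return tibble of class `grid_charges`: grid columns plus `q_s` (e).
#' @export
project_mm_to_grid <- function(mm_far, grid, qm, order = 1L, op = NULL) {
  if (is.null(op)) op <- esp_operator(grid, qm, order)
  if (op$order != order) {
    rlang::abort("esp_operator order does not match requested order",
                 class = "qmmbed_validation_error")
  }
  Fv <- .field_vector(local_field(mm_far, qm, order))
  out <- tibble::as_tibble(grid)
  out$q_s <- drop(t(op$pinv) %*% Fv)
  class(out) <- c("grid_charges", class(tibble::tibble()))
  out
}
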