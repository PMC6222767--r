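#' Classical polarizable surrogate backend
#'
#' A self-contained classical stand-in for an SCF/TDDFT engine that fulfils
#' the full backend contract, so every embedding model, switching scheme and
#' benchmark in this package runs without quantum chemistry. The "electron
#' density" of a QM region is a distributed set of point populations:
#' \itemize{
#'   \item a core population on each nucleus,
#'   \item bond satellite populations displaced along each covalent bond
#'     (giving the molecule permanent atomic dipoles, quadrupoles and higher
#'     moments, so multipole-truncated representations are genuinely
#'     approximate),
#'   \item six small axial populations per atom through which induced
#'     dipoles are realized.
#' }
#' Self-consistency is a variational linear-response model: atomic charges
#' flow under the external site potentials against a charge-equilibration
#' hardness matrix (atomic idempotentials on the diagonal, Klopman-Ohno
#' screened Coulomb off it, total charge conserved), and induced atomic
#' dipoles follow isotropic polarizabilities. The converged state minimizes
#' the response functional, so the polarization energy (converged minus
#' first-cycle) is non-positive for any starting density, mirroring the SCF
#' variational principle. Excited states are modelled as fixed
#' charge-transfer difference densities between distant atom pairs on top of
#' configurable gas-phase gaps; their energies shift linearly in the
#' embedding potential, as TDDFT states do with static embedding charges.
#'
#' @param satellite_len bond-satellite displacement from the nucleus (bohr).
#' @param satellite_pop satellite population per bond for heavy atoms (e).
#' @param satellite_pop_h same for hydrogen.
#' @param axial_delta displacement of the axial response points (bohr).
#' @param axial_base resting population of each axial point (e).
#' @param bond_scale bond perception: bonded if distance is below
#'   `bond_scale` times the covalent-radius sum.
#' @param exc_gap_ev gas-phase excitation energy of the first state (eV).
#' @param exc_gap_step_ev spacing of subsequent gas-phase states (eV).
#' @param exc_transfer charge transferred between the donor/acceptor atom
#'   pair in an excitation (e).
#' @param hardness_scale,alpha_scale global scale factors on the element
#'   hardness and polarizability tables.
#' @return backend object of class `surrogate_backend`.
#' @export
surrogate_backend <- function(satellite_len = 0.5, satellite_pop = 0.30,
                              satellite_pop_h = 0.15, axial_delta = 0.10,
                              axial_base = 0.01, bond_scale = 1.25,
                              exc_gap_ev = 2.3, exc_gap_step_ev = 0.4,
                              exc_transfer = 0.1, hardness_scale = 1,
                              alpha_scale = 1) {
  structure(
    list(satellite_len = satellite_len, satellite_pop = satellite_pop,
         satellite_pop_h = satellite_pop_h, axial_delta = axial_delta,
         axial_base = axial_base, bond_scale = bond_scale,
         exc_gap_ev = exc_gap_ev, exc_gap_step_ev = exc_gap_step_ev,
         exc_transfer = exc_transfer, hardness_scale = hardness_scale,
         alpha_scale = alpha_scale),
    class = c("surrogate_backend", "qmm_backend"))
}

#' @export
backend_capabilities.surrogate_backend <- function(backend) {
  list(scf = TRUE, esp_on_points = TRUE, density_charge_interaction = TRUE,
       tddft = TRUE)
}

# ---- base molecule model ----------------------------------------------------

# Distributed base density + response parameters for a QM region.
# All positions in bohr.
.surrogate_base <- function(backend, qm) {
  n <- nrow(qm)
  R <- .coords_bohr(qm)
  rcov <- .element_lookup(qm$element, "r_cov") * qmm_constants$bohr_per_angstrom
  # base atomic charges: force-field charges if present, else spread the net
  # charge Z-weighted
  q_base <- if (!anyNA(qm$q_ref)) qm$q_ref
            else attr(qm, "net_charge") * qm$Z / sum(qm$Z)
  N_atom <- qm$Z - q_base
  # bond perception
  bonds <- list()
  if (n > 1L) {
    for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
      d <- sqrt(sum((R[a, ] - R[b, ])^2))
      if (d <= backend$bond_scale * (rcov[a] + rcov[b]) && d > 1e-6) {
        bonds[[length(bonds) + 1L]] <- c(a, b)
      }
    }
  }
  pts_x <- c(); pts_y <- c(); pts_z <- c(); pts_n <- c(); pts_owner <- c()
  pts_kind <- c()
  add <- function(p, nn, owner, kind) {
    pts_x <<- c(pts_x, p[1]); pts_y <<- c(pts_y, p[2]); pts_z <<- c(pts_z, p[3])
    pts_n <<- c(pts_n, nn); pts_owner <<- c(pts_owner, owner)
    pts_kind <<- c(pts_kind, kind)
  }
  center_pop <- N_atom - 6 * backend$axial_base
  for (bd in bonds) {
    for (k in 1:2) {
      a <- bd[k]; b <- bd[3L - k]
      p <- if (qm$element[a] == "H") backend$satellite_pop_h
           else backend$satellite_pop
      p <- min(p, max(center_pop[a] - 0.05, 0) )
      if (p > 0) {
        u <- (R[b, ] - R[a, ]); u <- u / sqrt(sum(u^2))
        add(R[a, ] + backend$satellite_len * u, p, a, "satellite")
        center_pop[a] <- center_pop[a] - p
      }
    }
  }
  for (a in seq_len(n)) {
    add(R[a, ], center_pop[a], a, "core")
    for (c in 1:3) for (sgn in c(1, -1)) {
      p <- R[a, ]; p[c] <- p[c] + sgn * backend$axial_delta
      add(p, backend$axial_base, a, "axial")
    }
  }
  pts <- tibble::tibble(x = pts_x, y = pts_y, z = pts_z, n = pts_n,
                        owner = as.integer(pts_owner), kind = pts_kind)
  # charge-flow distribution weights: charge flows in and out of the whole
  # atomic cloud, so the flow couples to the potential averaged over it
  w <- numeric(nrow(pts))
  for (a in seq_len(n)) {
    sel <- pts$owner == a
    if (N_atom[a] > 0.1) w[sel] <- pts$n[sel] / N_atom[a]
    else w[sel & pts$kind == "core"] <- 1
  }
  pts$w <- w
  # charge-flow hardness matrix (Klopman-Ohno screened)
  eta <- .element_lookup(qm$element, "hardness") * backend$hardness_scale
  H <- diag(eta, n)
  if (n > 1L) {
    for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
      r2 <- sum((R[a, ] - R[b, ])^2)
      gamma <- ((1 / eta[a] + 1 / eta[b]) / 2)^2
      H[a, b] <- H[b, a] <- 1 / sqrt(r2 + gamma)
    }
  }
  alpha <- .element_lookup(qm$element, "alpha") * backend$alpha_scale
  list(qm = qm, R = R, pts = pts, H = H, alpha = alpha, q_base = q_base,
       n_elec = sum(N_atom), bonds = bonds)
}

# excitation donor/acceptor pairs: atom pairs ordered by decreasing distance
.surrogate_exc_pairs <- function(base, n_states) {
  n <- nrow(base$qm)
  if (n < 2L) {
    rlang::abort("surrogate excitations need at least two QM atoms",
                 class = "qmmbed_backend_error")
  }
  pr <- t(utils::combn(n, 2L))
  d <- sqrt(rowSums((base$R[pr[, 1], , drop = FALSE] -
                     base$R[pr[, 2], , drop = FALSE])^2))
  ord <- order(-d, pr[, 1], pr[, 2])
  pr <- pr[ord, , drop = FALSE]
  if (n_states > nrow(pr)) {
    rlang::abort("more states requested than donor/acceptor pairs available",
                 class = "qmmbed_backend_error")
  }
  pr[seq_len(n_states), , drop = FALSE]
}

# ---- density handle ---------------------------------------------------------

.surrogate_density <- function(backend, base, dq, dip) {
  pts <- base$pts
  delta <- backend$axial_delta
  # charge flow scales each atom's whole cloud; induced (charge-)dipoles
  # shift population between the axial points
  for (a in seq_len(nrow(base$qm))) {
    sel <- pts$owner == a
    pts$n[sel] <- pts$n[sel] - dq[a] * pts$w[sel]
    ax <- which(pts$owner == a & pts$kind == "axial")
    # axial order: +x, -x, +y, -y, +z, -z
    for (c in 1:3) {
      pts$n[ax[2 * c - 1]] <- pts$n[ax[2 * c - 1]] - dip[a, c] / (2 * delta)
      pts$n[ax[2 * c]] <- pts$n[ax[2 * c]] + dip[a, c] / (2 * delta)
    }
  }
  structure(
    list(backend = backend, base = base, pts = pts, dq = dq, dip = dip),
    class = "surrogate_density")
}

#' @export
print.surrogate_density <- function(x, ...) {
  cat(sprintf(
    "<surrogate_density> %d atoms, %d density points, %.6f electrons\n",
    nrow(x$base$qm), nrow(x$pts), sum(x$pts$n)))
  invisible(x)
}

#' @export
density_matrix.surrogate_density <- function(density) diag(density$pts$n)

#' @export
overlap_matrix.surrogate_density <- function(density) {
  diag(nrow(density$pts))
}

#' @export
moment_matrices.surrogate_density <- function(density) {
  list(diag(density$pts$x), diag(density$pts$y), diag(density$pts$z))
}

#' @export
basis_atoms.surrogate_density <- function(density) density$pts$owner

#' @export
electron_count.surrogate_density <- function(density) sum(density$pts$n)

# potential of the density (nuclei + electron points) at targets (bohr)
.surrogate_potential <- function(density, targets) {
  if (nrow(targets) == 0L) return(numeric(0))
  qm <- density$base$qm
  nuc <- density$base$R
  d2n <- outer(rowSums(targets^2), rowSums(nuc^2), "+") -
    2 * targets %*% t(nuc)
  if (any(d2n < 1e-12)) {
    rlang::abort("evaluation point coincides with a nucleus",
                 class = "qmmbed_singular_error")
  }
  phi <- drop((1 / sqrt(d2n)) %*% qm$Z)
  ep <- cbind(density$pts$x, density$pts$y, density$pts$z)
  d2e <- outer(rowSums(targets^2), rowSums(ep^2), "+") - 2 * targets %*% t(ep)
  phi - drop((1 / sqrt(pmax(d2e, 1e-12))) %*% density$pts$n)
}

#' @export
esp_on_points.surrogate_density <- function(density, qm, points) {
  pts <- if (inherits(points, "esp_grid") || is.data.frame(points)) {
    .coords_bohr(points)
  } else {
    as.matrix(points) * qmm_constants$bohr_per_angstrom
  }
  .surrogate_potential(density, pts)
}

#' @export
density_charge_interaction.surrogate_density <- function(density, qm, charges) {
  if (nrow(charges) == 0L) return(0)
  q <- if ("q_eff" %in% names(charges)) charges$q_eff else charges$q
  sum(q * .surrogate_potential(density, .coords_bohr(charges)))
}

# ---- SCF --------------------------------------------------------------------

# One-electron external potential v_k of an embedding operator, per unit
# electron population, at arbitrary points (bohr) with given owner atoms:
# -phi from the operator's point charges, plus the site-Taylor one-electron
# term of a site-field (Mulliken long-range) operator.
.point_v <- function(operator, base, points, owner) {
  v <- numeric(nrow(points))
  if (is.null(operator) || nrow(points) == 0L) return(v)
  ch <- operator$charges
  if (!is.null(ch) && nrow(ch)) {
    C <- .coords_bohr(ch)
    d2 <- outer(rowSums(points^2), rowSums(C^2), "+") - 2 * points %*% t(C)
    v <- v - drop((1 / sqrt(pmax(d2, 1e-12))) %*% ch$q)
  }
  if (!is.null(operator$site_field)) {
    sf <- operator$site_field
    E <- cbind(sf$ex, sf$ey, sf$ez)
    dr <- points - base$R[owner, , drop = FALSE]
    v <- v - sf$phi[owner] + rowSums(dr * E[owner, , drop = FALSE])
  }
  v
}

# response functional for state (dq, dip) with coupling vectors (b_q, b_d)
.response_energy <- function(base, dq, dip, b_q, b_d) {
  0.5 * drop(t(dq) %*% base$H %*% dq) +
    sum(rowSums(dip^2) / (2 * base$alpha)) +
    sum(dq * b_q) + sum(dip * b_d)
}

#' @export
converged_scf.surrogate_backend <- function(backend, qm, operator = NULL,
                                            initial = NULL) {
  base <- .surrogate_base(backend, qm)
  n <- nrow(qm)
  pts_xyz <- cbind(base$pts$x, base$pts$y, base$pts$z)
  v <- .point_v(operator, base, pts_xyz, base$pts$owner)
  # static part: base density plus nuclei in the operator potential
  e_static <- sum(base$pts$n * v)
  if (!is.null(operator)) {
    ch <- operator$charges
    if (!is.null(ch) && nrow(ch)) {
      e_static <- e_static + sum(qm$Z * local_field(ch, qm, 0L)$phi)
    }
    if (!is.null(operator$site_field)) {
      e_static <- e_static + sum(qm$Z * operator$site_field$phi)
    }
  }
  # linear coupling of the response coordinates to the operator: charge flow
  # sees the cloud-averaged potential, induced dipoles the finite-difference
  # potential across the axial pair
  b_q <- vapply(seq_len(n), function(a) {
    sel <- base$pts$owner == a
    -sum(base$pts$w[sel] * v[sel])
  }, numeric(1))
  b_d <- matrix(0, n, 3)
  delta <- backend$axial_delta
  for (a in seq_len(n)) {
    ax <- which(base$pts$owner == a & base$pts$kind == "axial")
    for (c in 1:3) {
      b_d[a, c] <- (v[ax[2 * c]] - v[ax[2 * c - 1]]) / (2 * delta)
    }
  }
  # converged response: constrained quadratic minimization
  if (n == 1L) {
    dq <- 0
  } else {
    kkt <- rbind(cbind(base$H, rep(1, n)), c(rep(1, n), 0))
    sol <- tryCatch(solve(kkt, c(-b_q, 0)), error = function(e) {
      rlang::abort(paste0("charge-flow equations singular: ",
                          conditionMessage(e)),
                   class = "qmmbed_backend_error")
    })
    dq <- sol[seq_len(n)]
  }
  dip <- -base$alpha * b_d
  e_conv <- e_static + .response_energy(base, dq, dip, b_q, b_d)
  if (is.null(initial)) {
    dq0 <- numeric(n); dip0 <- matrix(0, n, 3)
  } else {
    stopifnot(inherits(initial, "surrogate_density"))
    dq0 <- initial$dq; dip0 <- initial$dip
  }
  e_first <- e_static + .response_energy(base, dq0, dip0, b_q, b_d)
  list(density = .surrogate_density(backend, base, dq, dip),
       e_first = e_first, e_conv = e_conv)
}

# diagonal one-electron matrix of a site-field operator over the basis points
.site_field_matrix_diag <- function(site_field, pts, R) {
  phi <- site_field$phi
  E <- cbind(site_field$ex, site_field$ey, site_field$ez)
  o <- pts$owner
  dr <- cbind(pts$x - R[o, 1], pts$y - R[o, 2], pts$z - R[o, 3])
  -phi[o] + rowSums(dr * E[o, , drop = FALSE])
}

#' One-electron matrix of an embedding operator in a density's basis
#'
#' For operators carrying a site-field term (the Mulliken long-range
#' models), returns the constant one-electron matrix `h` such that
#' `Tr(P h)` is the electronic part of the multipolar long-range energy for
#' any density matrix `P` over that basis; the nuclear part is the
#' operator's `nuclear_shift`.
#'
#' @param operator an embedding operator with a `site_field` component.
#' @param density a density handle supplying the basis.
#' @return a square matrix (diagonal for the surrogate's point basis).
#' @export
operator_matrix <- function(operator, density) {
  if (is.null(operator$site_field)) {
    rlang::abort("operator has no one-electron (site-field) component",
                 class = "qmmbed_validation_error")
  }
  stopifnot(inherits(density, "surrogate_density"))
  diag(.site_field_matrix_diag(operator$site_field, density$pts,
                               density$base$R))
}

# ---- excitations ------------------------------------------------------------

#' @export
excitation_energies.surrogate_density <- function(density, qm, operator = NULL,
                                                  n_states = 1L) {
  backend <- density$backend
  base <- density$base
  pairs <- .surrogate_exc_pairs(base, n_states)
  t_e <- backend$exc_transfer
  gaps <- backend$exc_gap_ev + backend$exc_gap_step_ev *
    (seq_len(n_states) - 1)
  shifts_au <- vapply(seq_len(n_states), function(s) {
    don <- pairs[s, 1]; acc <- pairs[s, 2]
    # charge-transfer difference density: t_e electrons leave the donor
    # bond region and arrive in the acceptor bond region (points displaced
    # from the nuclei along the donor-acceptor axis)
    u <- base$R[acc, ] - base$R[don, ]
    u <- u / sqrt(sum(u^2))
    p <- rbind(base$R[don, ] + 0.5 * u, base$R[acc, ] - 0.5 * u)
    v <- .point_v(operator, base, p, owner = c(don, acc))
    -t_e * v[1] + t_e * v[2]
  }, numeric(1))
  gaps + shifts_au * qmm_constants$ev_per_hartree
}
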