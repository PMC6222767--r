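#' Generate a synthetic TIP3P-style water box around a solute
#'
#' Rigid three-site waters (r(OH) = 0.9572 angstrom, HOH angle 104.52
#' degrees, charges O -0.834 e / H +0.417 e, neutral per molecule) are
#' placed at random positions and orientations in a cubic box centred on
#' the solute. Placement rejects oxygens closer than `oo_min` to another
#' oxygen or `exclusion_radius` to any solute atom. With
#' `orientation_bias = "anion"`, waters near the solute are preferentially
#' oriented with their dipole (hydrogen side) pointing at it, emulating the
#' first-shell ordering around an anion that makes hydrogens on average
#' slightly closer than oxygens. Each water is one charge group.
#'
#' @param n_waters number of waters.
#' @param box_length cube edge (angstrom).
#' @param solute optional [qm_region()] at the box centre.
#' @param exclusion_radius minimum O-to-solute-atom distance (angstrom).
#' @param oo_min minimum O-O distance (angstrom).
#' @param orientation_bias `"none"` or `"anion"`.
#' @param seed integer seed; the same seed reproduces the same box.
#' @return an [mm_charges()] with 3 `n_waters` charges in `n_waters` groups
#'   (labels `OW`/`HW`).
#' @export
generate_water_box <- function(n_waters, box_length, solute = NULL,
                               exclusion_radius = 2.4, oo_min = 2.5,
                               orientation_bias = c("none", "anion"),
                               seed = 1L) {
  orientation_bias <- match.arg(orientation_bias)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(as.integer(seed))
  }
  center <- if (is.null(solute)) c(0, 0, 0) else colMeans(.coords_ang(solute))
  sol_xyz <- if (is.null(solute)) matrix(0, 0, 3) else .coords_ang(solute)
  half <- box_length / 2
  # rigid TIP3P geometry in a local frame: bisector along +z
  th <- (104.52 / 2) * pi / 180
  local_h <- rbind(c(0.9572 * sin(th), 0, 0.9572 * cos(th)),
                   c(-0.9572 * sin(th), 0, 0.9572 * cos(th)))
  o_pos <- matrix(NA_real_, n_waters, 3)
  placed <- 0L
  tries <- 0L; max_tries <- 2000L * n_waters
  while (placed < n_waters) {
    tries <- tries + 1L
    if (tries > max_tries) {
      rlang::abort(sprintf(
        "packing failure: placed %d of %d waters in a %.1f angstrom box",
        placed, n_waters, box_length), class = "qmmbed_packing_error")
    }
    p <- stats::runif(3, -half, half) + center
    if (nrow(sol_xyz) &&
        min(sqrt(rowSums(sweep(sol_xyz, 2, p, "-")^2))) < exclusion_radius) next
    if (placed > 0L &&
        min(sqrt(rowSums(sweep(o_pos[seq_len(placed), , drop = FALSE],
                               2, p, "-")^2))) < oo_min) next
    placed <- placed + 1L
    o_pos[placed, ] <- p
  }
  coords <- matrix(NA_real_, 3L * n_waters, 3)
  for (w in seq_len(n_waters)) {
    o <- o_pos[w, ]
    d <- sqrt(sum((o - center)^2))
    biased <- orientation_bias == "anion" &&
      stats::runif(1) < exp(-max(0, d - exclusion_radius) / 2.5)
    Rm <- if (biased) {
      u <- (center - o) / max(d, 1e-9)
      # point the bisector (+z) at the solute, with a random spin about it
      # and a small random tilt
      .rot_z_to(u) %*% .rot_axis(c(0, 0, 1), stats::runif(1, 0, 2 * pi)) |>
        (\(m) .rot_axis(.rand_unit(), abs(stats::rnorm(1, 0, 15 * pi / 180))) %*% m)()
    } else {
      .rand_rotation()
    }
    coords[3 * w - 2, ] <- o
    coords[3 * w - 1, ] <- o + drop(Rm %*% local_h[1, ])
    coords[3 * w, ] <- o + drop(Rm %*% local_h[2, ])
  }
  mm <- mm_charges(coords,
                   q = rep(c(-0.834, 0.417, 0.417), n_waters),
                   group = rep(seq_len(n_waters), each = 3L))
  attr(mm, "labels") <- rep(c("OW", "HW", "HW"), n_waters)
  mm
}

.rand_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# uniform random rotation from a normalized quaternion
.rand_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# Rodrigues rotation about a unit axis
.rot_axis <- function(axis, angle) {
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}

# rotation taking +z onto unit vector u
.rot_z_to <- function(u) {
  z <- c(0, 0, 1)
  c_ <- sum(z * u)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) return(.rot_axis(c(1, 0, 0), pi))
  axis <- c(z[2] * u[3] - z[3] * u[2], z[3] * u[1] - z[1] * u[3],
            z[1] * u[2] - z[2] * u[1])
  axis <- axis / sqrt(sum(axis^2))
  .rot_axis(axis, acos(c_))
}

#' Built-in benchmark solutes
#'
#' `solute_acetate()` returns an acetate anion (CH3COO-, 7 atoms) with
#' CHARMM-style reference charges -- the default desk-scale stand-in for a
#' solvated organic anion. `solute_chloride()` returns a bare chloride ion.
#' `solute_oxyluciferin()` loads the larger synthetic oxyluciferin-anion
#' geometry shipped with the package (coordinates generated from its
#' connectivity with a distance-geometry/force-field pipeline, charges from
#' a Gasteiger-type scheme normalized to the net charge; a stand-in, not an
#' experimental structure).
#'
#' @return a [qm_region()] with reference charges and net charge -1.
#' @export
solute_acetate <- function() {
  th <- 63 * pi / 180
  tet <- 109.471 * pi / 180
  c1 <- c(-1.52, 0, 0)
  hs <- t(vapply(c(90, 210, 330) * pi / 180, function(az) {
    c1 + 1.09 * c(cos(tet), sin(tet) * cos(az), sin(tet) * sin(az))
  }, numeric(3)))
  coords <- rbind(
    c(0, 0, 0),                        # carboxyl C
    1.26 * c(cos(th), sin(th), 0),     # O
    1.26 * c(cos(th), -sin(th), 0),    # O
    c1,                                # methyl C
    hs)
  qm_region(c("C", "O", "O", "C", "H", "H", "H"), coords,
            q_ref = c(0.62, -0.76, -0.76, -0.37, 0.09, 0.09, 0.09),
            net_charge = -1L)
}

#' @rdname solute_acetate
#' @export
solute_chloride <- function() {
  qm_region("Cl", matrix(0, 1, 3), q_ref = -1, net_charge = -1L)
}

#' @rdname solute_acetate
#' @export
solute_oxyluciferin <- function() {
  path <- system.file("extdata", "oxyluciferin_anion_synthetic.xyzq",
                      package = "qmmbed", mustWork = TRUE)
  read_xyzq(path)$qm
}

#' Generate seeded benchmark configurations
#'
#' Builds `n_configs` water boxes around a common solute from consecutive
#' seeds, emulating independent snapshots of a solvated system.
#'
#' @param solute a [qm_region()].
#' @param n_configs number of configurations.
#' @param n_waters,box_length,orientation_bias,... passed to
#'   [generate_water_box()].
#' @param seed base seed; configuration i uses `seed + i - 1`.
#' @return list of `list(qm = , mm = )` pairs.
#' @export
benchmark_configs <- function(solute, n_configs = 10, n_waters = 200,
                              box_length = 30, orientation_bias = "anion",
                              seed = 1L, ...) {
  lapply(seq_len(n_configs), function(i) {
    list(qm = solute,
         mm = generate_water_box(n_waters, box_length, solute,
                                 orientation_bias = orientation_bias,
                                 seed = seed + i - 1L, ...))
  })
}
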