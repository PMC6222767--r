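be <- surrogate_backend()
qm_ac <- solute_acetate()
den_ac <- converged_scf(be, qm_ac, NULL)$density
grid_ac <- build_esp_grid(qm_ac)

test_that("mechanical embedding is the bare Coulomb sum", {
  qm <- qm_region("H", matrix(0, 1, 3), q_ref = 1)
  at <- function(x_ang) mm_charges(matrix(c(x_ang, 0, 0), 1), -1, 1L)
  expect_equal(mechanical_energy(qm, at(ANG_BOHR)), -627.509474)
  expect_equal(mechanical_energy(qm, at(1)), -627.509474 * ANG_BOHR,
               tolerance = 1e-12) # about -332.064 kcal/mol
  empty <- mm_charges(matrix(0, 0, 3), numeric(0), integer(0))
  expect_equal(mechanical_energy(qm, empty), 0)
  no_ff <- qm_region("H", matrix(0, 1, 3))
  expect_error(mechanical_energy(no_ff, at(1)),
               class = "qmmbed_validation_error")
})

test_that("density embedding approaches the monopole limit at long range", {
  empty <- mm_charges(matrix(0, 0, 3), numeric(0), integer(0))
  expect_equal(density_embedding_energy(den_ac, qm_ac, empty), 0)
  # monopole limit, with the distance measured from the center of charge
  # (the dipole of a charged distribution vanishes about that point)
  pts <- den_ac$pts
  coc <- (colSums(qm_ac$Z * den_ac$base$R) -
            colSums(pts$n * cbind(pts$x, pts$y, pts$z))) / (-1)
  probe <- c(100, 0, 0) + coc # bohr
  mm <- mm_charges(matrix(probe * ANG_BOHR, 1), q = 1, group = 1L)
  e <- density_embedding_energy(den_ac, qm_ac, mm) / AU_KCAL
  expect_lt(abs(e - (-1 / 100)) / abs(e), 1e-3)
  on_nucleus <- mm_charges(matrix(c(qm_ac$x[1], qm_ac$y[1], qm_ac$z[1]), 1),
                           1, 1L)
  expect_error(density_embedding_energy(den_ac, qm_ac, on_nucleus),
               class = "qmmbed_singular_error")
})

test_that("multipolar energy contracts moments with the local field", {
  M <- mulliken_multipoles(den_ac, qm_ac, order = 1)
  zero_F <- local_field(mm_charges(matrix(0, 0, 3), numeric(0), integer(0)),
                        qm_ac, 1)
  expect_equal(multipolar_energy(M, zero_F), 0)
  # single site with q = -1 in a potential of 0.5 a.u.
  one <- qm_region("Cl", matrix(0, 1, 3))
  mm <- mm_charges(matrix(c(2 * ANG_BOHR, 0, 0), 1), 1, 1L)
  F1 <- local_field(mm, one, 1)
  M1 <- structure(tibble::tibble(site = 1L, element = "Cl", x = 0, y = 0,
                                 z = 0, q = -1, mux = 0, muy = 0, muz = 0),
                  order = 1L, method = "esp",
                  class = c("multipole_set", class(tibble::tibble())))
  expect_equal(multipolar_energy(M1, F1), -0.5 * AU_KCAL)
  # a dipole perpendicular to the field contributes nothing
  M1$muy <- 5
  expect_equal(multipolar_energy(M1, F1), -0.5 * AU_KCAL)
  M1$muy <- 0; M1$mux <- 1
  expect_equal(multipolar_energy(M1, F1), (-0.5 - 0.25) * AU_KCAL)
  expect_error(multipolar_energy(M, F1), class = "qmmbed_validation_error")
})

test_that("MMLC reduces to mechanical embedding of the far field", {
  empty <- mm_charges(matrix(0, 0, 3), numeric(0), integer(0))
  expect_equal(mmlc_correction(qm_ac, empty), 0)
  mm <- generate_water_box(20, 14, qm_ac, seed = 2)
  expect_equal(mmlc_correction(qm_ac, mm), mechanical_energy(qm_ac, mm))
  # monopole limit: net -1 QM region vs one far charge, measured from the
  # center of the reference-charge distribution
  coc <- colSums(qm_ac$q_ref * cbind(qm_ac$x, qm_ac$y, qm_ac$z)) / -1
  far_pos <- c(50, 0, 0) + coc
  far <- mm_charges(matrix(far_pos, 1), q = 0.5, group = 1L)
  e <- mmlc_correction(qm_ac, far) / AU_KCAL
  expect_lt(abs(e - (-0.5 / (50 / ANG_BOHR))) / abs(e), 1e-3)
})

test_that("hybrid energy has the right limits and exact decomposition", {
  mm <- generate_water_box(40, 16, qm_ac, orientation_bias = "anion",
                           seed = 9)
  e_ref <- density_embedding_energy(den_ac, qm_ac, mm)
  # cutoff beyond the box: every model collapses onto the reference
  for (model in c("truncation", "truncation_mmlc", "mulcd", "espcd")) {
    rep_big <- hybrid_energy(den_ac, qm_ac, mm, model, "step", 1e3,
                             grid = grid_ac)
    expect_equal(rep_big$total, e_ref, tolerance = 1e-10)
  }
  # zero cutoff: pure multipolar energy over all charges
  M <- mulliken_multipoles(den_ac, qm_ac, 1)
  rep0 <- hybrid_energy(den_ac, qm_ac, mm, "mulcd", "lrec", 0,
                        mode = "atom")
  expect_equal(rep0$total, multipolar_energy(M, local_field(mm, qm_ac, 1)),
               tolerance = 1e-10)
  expect_equal(rep0$short_range, 0)
  # additive decomposition for every model and scheme
  for (model in c("truncation", "truncation_mmlc", "mulc", "mulcd",
                  "espc", "espcd")) {
    for (scheme in c("step", "lrec")) {
      rep_ <- hybrid_energy(den_ac, qm_ac, mm, model, scheme, 8,
                            grid = grid_ac)
      expect_equal(rep_$total, rep_$short_range + rep_$long_range + rep_$mmlc,
                   tolerance = 1e-10)
    }
  }
  expect_error(hybrid_energy(den_ac, qm_ac, mm, "mechanical", "lrec", 8),
               class = "qmmbed_validation_error")
})

test_that("smooth switching removes the cutoff discontinuity that Step has", {
  qm <- solute_chloride() # single site: the probe's x is its cutoff distance
  den <- converged_scf(be, qm, NULL)$density
  grid <- build_esp_grid(qm)
  mm0 <- generate_water_box(30, 16, qm, seed = 3)
  energy_with_probe <- function(r, model, scheme) {
    probe <- mm_charges(matrix(c(r, 0, 0), 1), q = -0.5, group = 99L)
    mm <- dplyr::bind_rows(mm0, probe)
    class(mm) <- class(mm0)
    hybrid_energy(den, qm, mm, model, scheme, 10, mode = "atom",
                  grid = grid)$total
  }
  eps <- 1e-9
  for (model in c("truncation", "espcd")) {
    for (scheme in c("lrec", "switch", "shift")) {
      jump <- abs(energy_with_probe(10 - eps, model, scheme) -
                  energy_with_probe(10 + eps, model, scheme))
      expect_lt(jump, 1e-6)
    }
  }
  # hard removal under Step: the jump is the probe's full interaction energy
  step_jump <- abs(energy_with_probe(10 - eps, "truncation", "step") -
                   energy_with_probe(10 + eps, "truncation", "step"))
  expect_gt(step_jump, 1)
})

test_that("embedding operators realize each model's far-field route", {
  mm <- generate_water_box(40, 16, qm_ac, orientation_bias = "anion",
                           seed = 13)
  split <- split_charges(partition_charges(mm, qm_ac, 8, "atom"), "lrec")
  op_tr <- build_embedding_operator("truncation", split, qm_ac)
  expect_equal(nrow(op_tr$charges), sum(split$near & abs(split$q_I) > 0))
  expect_null(op_tr$site_field)
  # espcd: grid charges appended
  op_esp <- build_embedding_operator("espcd", split, qm_ac, grid = grid_ac)
  expect_equal(nrow(op_esp$charges),
               nrow(op_tr$charges) + nrow(grid_ac))
  expect_error(build_embedding_operator("espcd", split, qm_ac),
               class = "qmmbed_validation_error")
  # SCF long-range energy through grid charges equals the multipolar
  # evaluation on the converged density (grid-projection identity at the
  # SCF solution)
  scf <- converged_scf(be, qm_ac, op_esp, initial = den_ac)
  gq <- op_esp$charges[-seq_len(nrow(op_tr$charges)), ]
  e_scf_long <- density_embedding_energy(scf$density, qm_ac, gq)
  fit <- fit_esp_multipoles(grid_ac, esp_on_points(scf$density, qm_ac,
                                                   grid_ac), qm_ac, 1)
  long_set <- split
  long_set$q_eff <- ifelse(long_set$near, long_set$q_II, long_set$q)
  e_eq16 <- multipolar_energy(fit$multipoles,
                              local_field(long_set, qm_ac, 1))
  expect_equal(e_scf_long, e_eq16, tolerance = 1e-8)
})

test_that("the Mulliken far-field operator is linear in the density matrix", {
  mm <- generate_water_box(40, 16, qm_ac, seed = 21)
  split <- split_charges(partition_charges(mm, qm_ac, 8, "atom"), "lrec")
  op <- build_embedding_operator("mulcd", split, qm_ac)
  expect_false(is.null(op$site_field))
  h <- operator_matrix(op, den_ac)
  long_set <- split
  long_set$q_eff <- ifelse(long_set$near, long_set$q_II, long_set$q)
  F_long <- local_field(long_set, qm_ac, 1)
  set.seed(5)
  for (i in 1:3) {
    den_i <- den_ac
    den_i$pts$n <- den_ac$pts$n * stats::runif(nrow(den_ac$pts), 0.5, 1.5)
    M_i <- mulliken_multipoles(den_i, qm_ac, 1)
    e13_elec <- multipolar_energy(M_i, F_long) / AU_KCAL -
      sum(qm_ac$Z * F_long$phi)
    expect_equal(sum(diag(density_matrix(den_i)) * diag(h)), e13_elec,
                 tolerance = 1e-10)
  }
})

test_that("polarization energy is zero at stationarity and never positive", {
  mm <- generate_water_box(40, 16, qm_ac, orientation_bias = "anion",
                           seed = 31)
  op_ref <- build_embedding_operator("reference", tibble::as_tibble(mm),
                                     qm_ac)
  den_ref <- converged_scf(be, qm_ac, op_ref)$density
  # stationary start: gas-phase operator with gas-phase density
  den_gas <- converged_scf(be, qm_ac, NULL)$density
  expect_equal(polarization_energy(be, qm_ac, NULL, den_gas), 0,
               tolerance = 1e-12)
  # variational bound for assorted operators
  split <- split_charges(partition_charges(mm, qm_ac, 6, "atom"), "lrec")
  ops <- list(
    NULL, op_ref,
    build_embedding_operator("truncation", split, qm_ac),
    build_embedding_operator("espcd", split, qm_ac, grid = grid_ac),
    build_embedding_operator("mulcd", split, qm_ac))
  for (op in ops) {
    expect_lte(polarization_energy(be, qm_ac, op, den_ref), 1e-12)
  }
  # gas-phase operator from the reference density: magnitude equals the
  # orbital-rotation energy recomputed independently from the response state
  pol <- polarization_energy(be, qm_ac, NULL, den_ref)
  base <- den_ref$base
  rot <- 0.5 * drop(t(den_ref$dq) %*% base$H %*% den_ref$dq) +
    sum(rowSums(den_ref$dip^2) / (2 * base$alpha))
  expect_equal(pol, -rot * AU_KCAL, tolerance = 1e-10)
  expect_lt(pol, 0)
})
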