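test_that("interaction tensor matches its closed form and homogeneity", {
  t1 <- interaction_tensor(c(0, 0, 0), c(2, 0, 0), order = 1)
  expect_equal(unname(t1), c(0.5, -0.25, 0, 0))
  t2 <- interaction_tensor(c(0, 0, 0), c(4, 0, 0), order = 1)
  expect_equal(t2[["m0"]], t1[["m0"]] / 2)       # degree -1
  expect_equal(t2[["m1x"]], t1[["m1x"]] / 4)     # degree -2
  expect_error(interaction_tensor(c(1, 1, 1), c(1, 1, 1)),
               class = "qmmbed_singular_error")
})

test_that("local fields are single-term tensors, symmetric and superposable", {
  site <- matrix(c(0, 0, 0), 1)
  q_at <- function(x) mm_charges(matrix(c(x * ANG_BOHR, 0, 0), 1), 1, 1L)
  F <- local_field(q_at(2), site, order = 1)
  expect_equal(F$phi, 0.5)
  expect_equal(c(F$ex, F$ey, F$ez), c(-0.25, 0, 0))
  # opposite charges symmetric about the site: zero potential, axial field
  mm2 <- mm_charges(rbind(c(2, 0, 0), c(-2, 0, 0)) * ANG_BOHR,
                    q = c(1, -1), group = c(1L, 2L))
  F2 <- local_field(mm2, site, order = 1)
  expect_equal(F2$phi, 0, tolerance = 1e-14)
  expect_equal(F2$ex, -0.5)
  expect_equal(c(F2$ey, F2$ez), c(0, 0))
  # superposition
  set.seed(7)
  mk <- function(n, g0) mm_charges(matrix(stats::rnorm(n * 3, sd = 6), ncol = 3),
                                   stats::runif(n, -1, 1), seq_len(n) + g0)
  a <- mk(8, 0L); b <- mk(5, 8L)
  both <- mm_charges(rbind(cbind(a$x, a$y, a$z), cbind(b$x, b$y, b$z)),
                     c(a$q, b$q), c(a$group, b$group))
  qm <- tiny_water_qm()
  Fa <- local_field(a, qm); Fb <- local_field(b, qm)
  Fab <- local_field(both, qm)
  expect_lt(max(abs(Fab$phi - (Fa$phi + Fb$phi))), 1e-14)
  expect_lt(max(abs(Fab$ex - (Fa$ex + Fb$ex))), 1e-14)
  expect_error(local_field(mm_charges(matrix(0, 1, 3), 1, 1L), site),
               class = "qmmbed_singular_error")
})

test_that("Mulliken analysis conserves charge and respects symmetry", {
  be <- surrogate_backend()
  # single closed-shell neutral atom: zero charge, zero dipole
  ne <- qm_region("O", matrix(0, 1, 3), q_ref = 0)
  d1 <- converged_scf(be, ne, NULL)$density
  m1 <- mulliken_multipoles(d1, ne, order = 1)
  expect_equal(m1$q, 0, tolerance = 1e-12)
  expect_equal(c(m1$mux, m1$muy, m1$muz), c(0, 0, 0), tolerance = 1e-12)
  # homonuclear diatomic: equal charges, equal-and-opposite bond dipoles
  o2 <- qm_region(c("O", "O"), rbind(c(0, 0, 0), c(1.21, 0, 0)))
  d2 <- converged_scf(be, o2, NULL)$density
  m2 <- mulliken_multipoles(d2, o2, order = 1)
  expect_equal(m2$q[1], m2$q[2], tolerance = 1e-12)
  expect_equal(m2$mux[1], -m2$mux[2], tolerance = 1e-12)
  expect_true(abs(m2$mux[1]) > 1e-3) # satellites give a real bond dipole
  # charge sums to the region's net charge for an asymmetric anion
  qm <- solute_acetate()
  d3 <- converged_scf(be, qm, NULL)$density
  m3 <- mulliken_multipoles(d3, qm, order = 1)
  expect_equal(sum(m3$q), attr(qm, "net_charge"), tolerance = 1e-10)
  expect_error(mulliken_multipoles(d3, qm, order = 2),
               class = "qmmbed_validation_error")
})

test_that("ESP grids have the constructed counts and pruning behaviour", {
  shells <- c(1.4, 1.6, 1.8, 2.0)
  one <- qm_region("O", matrix(0, 1, 3))
  g1 <- build_esp_grid(one, shells, density = 1)
  r_vdw <- 1.52
  expected <- sum(vapply(shells, function(s) round(4 * pi * (s * r_vdw)^2),
                         numeric(1)))
  expect_equal(nrow(g1), expected)
  radii <- sqrt(g1$x^2 + g1$y^2 + g1$z^2)
  expect_true(all(radii >= 1.4 * r_vdw - 1e-9))
  # far-separated atoms: disjoint union of the single-atom grids
  two_far <- qm_region(c("O", "O"), rbind(c(0, 0, 0), c(50, 0, 0)))
  expect_equal(nrow(build_esp_grid(two_far, shells, 1)), 2L * expected)
  # overlapping atoms: strictly fewer points than the disjoint sum
  two_close <- qm_region(c("O", "O"), rbind(c(0, 0, 0), c(1.21, 0, 0)))
  expect_lt(nrow(build_esp_grid(two_close, shells, 1)), 2L * expected)
})

test_that("the SVD fit recovers exactly representable sources", {
  one <- qm_region("O", matrix(0, 1, 3))
  grid <- build_esp_grid(one)
  gp <- cbind(grid$x, grid$y, grid$z) / ANG_BOHR
  # potential of a -1 e point charge at the site
  phi_q <- -1 / sqrt(rowSums(gp^2))
  fit <- fit_esp_multipoles(grid, phi_q, one, order = 1)
  expect_equal(fit$multipoles$q, -1, tolerance = 1e-10)
  expect_equal(abs(fit$multipoles$mux) + abs(fit$multipoles$muy) +
               abs(fit$multipoles$muz), 0, tolerance = 1e-10)
  # known charge + dipole source: recovered at order 1 to 1e-10
  mu <- c(0.3, -0.2, 0.5)
  phi_qmu <- phi_q * 0.4 + gp %*% mu * (-1) / rowSums(gp^2)^1.5
  # the site-dipole channel couples through T1 = (r_A - r_s)/r^3 = -r_s/r^3
  fit1 <- fit_esp_multipoles(grid, drop(phi_qmu), one, order = 1)
  expect_equal(fit1$multipoles$q, -0.4, tolerance = 1e-10)
  expect_equal(c(fit1$multipoles$mux, fit1$multipoles$muy,
                 fit1$multipoles$muz), mu, tolerance = 1e-10)
  expect_lt(fit1$residual, 1e-10)
  # all-zero targets give zero moments (valid, not an error)
  fit0 <- fit_esp_multipoles(grid, rep(0, nrow(grid)), one, order = 1)
  expect_equal(fit0$multipoles$q, 0)
  # scale equivariance
  fit_s <- fit_esp_multipoles(grid, drop(phi_qmu) * 3.5, one, order = 1)
  expect_equal(fit_s$multipoles$q, 3.5 * fit1$multipoles$q, tolerance = 1e-10)
  expect_equal(fit_s$multipoles$mux, 3.5 * fit1$multipoles$mux,
               tolerance = 1e-10)
})

test_that("order-1 fits dominate order-0 fits for richer sources", {
  be <- surrogate_backend()
  qm <- tiny_oh_qm()
  den <- converged_scf(be, qm, NULL)$density
  grid <- build_esp_grid(qm)
  phi <- esp_on_points(den, qm, grid)
  f0 <- fit_esp_multipoles(grid, phi, qm, order = 0)
  f1 <- fit_esp_multipoles(grid, phi, qm, order = 1)
  expect_lt(f1$residual, f0$residual)
  # underdetermined systems are rejected
  small <- grid[1:3, ]
  class(small) <- class(grid)
  expect_error(fit_esp_multipoles(small, phi[1:3], qm, 1),
               class = "qmmbed_validation_error")
})

test_that("grid projection is linear and reproduces the energy identity", {
  sys <- random_esp_system(101)
  gq0 <- project_mm_to_grid(sys$mm, sys$grid, sys$qm, order = 1)
  empty <- mm_charges(matrix(0, 0, 3), numeric(0), integer(0))
  expect_equal(project_mm_to_grid(empty, sys$grid, sys$qm, 1)$q_s,
               rep(0, nrow(sys$grid)))
  mm2 <- sys$mm
  mm2$q <- 2 * mm2$q
  gq2 <- project_mm_to_grid(mm2, sys$grid, sys$qm, order = 1)
  expect_equal(gq2$q_s, 2 * gq0$q_s, tolerance = 1e-12)
  # mismatched operator order is rejected
  op0 <- esp_operator(sys$grid, sys$qm, order = 0)
  expect_error(project_mm_to_grid(sys$mm, sys$grid, sys$qm, 1, op = op0),
               class = "qmmbed_validation_error")
})

test_that("multipolar energy equals the grid-projected energy on random systems", {
  for (seed in 1:25) {
    sys <- random_esp_system(seed)
    for (ord in 0:1) {
      fit <- fit_esp_multipoles(sys$grid, sys$phi, sys$qm, order = ord)
      e_multipole <- multipolar_energy(fit$multipoles,
                                       local_field(sys$mm, sys$qm, ord))
      gq <- project_mm_to_grid(sys$mm, sys$grid, sys$qm, order = ord)
      e_grid <- sum(gq$q_s * sys$phi) * AU_KCAL
      expect_equal(e_grid, e_multipole, tolerance = 1e-10)
    }
  }
})
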