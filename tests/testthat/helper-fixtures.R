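# shared fixtures, all built in code

AU_KCAL <- 627.509474
ANG_BOHR <- 0.529177210903

tiny_water_qm <- function() {
  th <- (104.52 / 2) * pi / 180
  qm_region(
    c("O", "H", "H"),
    rbind(c(0, 0, 0),
          c(0.9572 * sin(th), 0, 0.9572 * cos(th)),
          c(-0.9572 * sin(th), 0, 0.9572 * cos(th))),
    q_ref = c(-0.834, 0.417, 0.417))
}

# diatomic anion with a strong permanent dipole, used where a compact
# multi-moment source is needed
tiny_oh_qm <- function() {
  qm_region(c("O", "H"), rbind(c(0, 0, 0), c(0.96, 0, 0)),
            q_ref = c(-1.1, 0.1), net_charge = -1L)
}

# random small site/grid/charge geometry for the grid-projection identity
random_esp_system <- function(seed) {
  set.seed(seed)
  n_sites <- sample(2:5, 1)
  repeat {
    sites <- matrix(stats::runif(n_sites * 3, -1.5, 1.5), ncol = 3)
    if (n_sites == 1L || min(stats::dist(sites)) > 0.8) break
  }
  qm <- qm_region(sample(c("C", "N", "O"), n_sites, replace = TRUE), sites)
  n_grid <- sample((4 * n_sites + 2):50, 1)
  gdir <- qmmbed:::.fibonacci_sphere(n_grid)
  gpts <- gdir * stats::runif(n_grid, 5, 8)
  grid <- tibble::tibble(x = gpts[, 1], y = gpts[, 2], z = gpts[, 3],
                         atom = 1L, shell = 1)
  class(grid) <- c("esp_grid", class(tibble::tibble()))
  n_mm <- sample(5:20, 1)
  mdir <- qmmbed:::.fibonacci_sphere(n_mm)
  mpts <- mdir * stats::runif(n_mm, 10, 20)
  mm <- mm_charges(mpts, q = stats::runif(n_mm, -1, 1),
                   group = seq_len(n_mm))
  list(qm = qm, grid = grid, mm = mm,
       phi = stats::rnorm(n_grid, sd = 0.1))
}

# independent switching-function oracle: expanded polynomial coefficients
# built by convolution, evaluated by Horner's rule
horner <- function(coef, x) {
  acc <- rep(0, length(x))
  for (c_ in rev(coef)) acc <- acc * x + c_
  acc
}

oracle_switch <- function(r, scheme, r_off, r_on = 0.75 * r_off) {
  out <- numeric(length(r))
  inside <- r <= r_off
  ri <- r[inside]
  out[inside] <- switch(
    scheme,
    step = 1,
    shift = {
      # (1 - u^2)^2 in powers of u = r/r_off
      cf <- convolve(c(1, 0, -1), rev(c(1, 0, -1)), type = "open")
      horner(cf, ri / r_off)
    },
    lrec = {
      # 1 - (2u^3 - 3u^2 + 1)^2 in powers of u = 1 - r/r_off
      p <- c(1, 0, -3, 2)
      cf <- -convolve(p, rev(p), type = "open")
      cf[1] <- cf[1] + 1
      horner(cf, 1 - ri / r_off)
    },
    switch = {
      a <- r_off^2; b <- r_on^2
      # (a - x)^2 (a + 2x - 3b) in powers of x = r^2
      cf <- convolve(convolve(c(a, -1), rev(c(a, -1)), type = "open"),
                     rev(c(a - 3 * b, 2)), type = "open")
      ifelse(ri <= r_on, 1, horner(cf, ri^2) / (a - b)^3)
    })
  out
}

# RMS (over probe directions) far-field error of a multipole set vs the
# exact density interaction, per distance
farfield_errors <- function(den, qm, M, order, dists_ang, n_dir = 26) {
  dirs <- qmmbed:::.fibonacci_sphere(n_dir)
  vapply(dists_ang, function(d) {
    e <- apply(dirs, 1, function(u) {
      mm <- mm_charges(matrix(u * d, 1), q = 1, group = 1L)
      density_embedding_energy(den, qm, mm) -
        multipolar_energy(M, local_field(mm, qm, order))
    })
    sqrt(mean(e^2))
  }, numeric(1))
}

loglog_slope <- function(y, x) unname(stats::coef(stats::lm(log(y) ~ log(x)))[2])
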