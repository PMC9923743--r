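test_that("forces vanish at the scanned dimer minimum and sum to zero", {
  m <- make_small_molecule("ppp_dimer")
  p <- m$params
  p$repulsion_a <- 290; p$repulsion_rho <- 0.35
  energy_at <- function(r) {
    g <- geometry(c("X", "X"), matrix(c(0, 0, 0, r, 0, 0), 2, 3,
                                      byrow = TRUE), charges = c(1, 1))
    scf_solve(ppp_integrals(g, p), 1, 1, mode = "restricted")$energy
  }
  ropt <- optimize(energy_at, c(1.8, 3.5), tol = 1e-10)$minimum
  g <- geometry(c("X", "X"), matrix(c(0, 0, 0, ropt, 0, 0), 2, 3,
                                    byrow = TRUE), charges = c(1, 1))
  sys <- md_system_ppp(p, surface = "ground", ground_mode = "restricted")
  st <- elec_init(sys, g)
  F <- compute_forces(sys, g, st, md_config(n_steps = 1))
  expect_lt(max(abs(F)), 1e-6)
  expect_equal(colSums(F), c(0, 0, 0), tolerance = 1e-9)
})

test_that("analytic and finite-difference forces agree on both surfaces", {
  toy <- get_toy_gas()
  for (surf in c("ground", "deltascf")) {
    sys <- if (surf == "ground") {
      md_system_ppp(toy$params, surface = "ground",
                    ground_mode = "restricted")
    } else {
      md_system_ppp(toy$params, surface = "deltascf",
                    excitation = toy$excitation)
    }
    st <- elec_init(sys, toy$geometry)
    Fa <- compute_forces(sys, toy$geometry, st, md_config(n_steps = 1))
    Ff <- compute_forces(sys, toy$geometry, st,
                         md_config(n_steps = 1,
                                   force_mode = "finite_difference"))
    expect_lt(max(abs(Fa - Ff)), 1e-6)
    expect_equal(colSums(Fa), c(0, 0, 0), tolerance = 1e-9)
  }
})

test_that("embedded analytic forces match finite differences", {
  toy <- get_toy()
  sys <- md_system_ppp(toy$params, sites = toy$sites, surface = "ground",
                       ground_mode = "restricted")
  st <- elec_init(sys, toy$geometry)
  Fa <- compute_forces(sys, toy$geometry, st, md_config(n_steps = 1))
  Ff <- compute_forces(sys, toy$geometry, st,
                       md_config(n_steps = 1,
                                 force_mode = "finite_difference"))
  expect_lt(max(abs(Fa - Ff)), 1e-6)
})

test_that("velocity Verlet preserves statics and respects the frozen mask", {
  sys <- md_system_harmonic(k = 0.5, center = c(0, 0, 0))
  g <- geometry("H", matrix(c(0, 0, 0), 1, 3))
  run <- run_md(sys, g, md_config(dt = 0.5, n_steps = 10, seed = 1),
                velocities = matrix(0, 1, 3))
  expect_equal(run$geometry$coords, g$coords, tolerance = 1e-14)

  g2 <- geometry("H", matrix(c(1, 0, 0), 1, 3))  # nonzero force
  run2 <- run_md(sys, g2, md_config(dt = 0.5, n_steps = 10, seed = 1,
                                    frozen_atom_indices = 1L),
                 velocities = matrix(0.1, 1, 3))
  expect_equal(run2$geometry$coords, g2$coords, tolerance = 1e-14)
  expect_equal(run2$velocities, matrix(0, 1, 3))
})

test_that("the harmonic oscillator period matches the closed form to 1%", {
  k <- 0.4
  m_au <- 1.00782503 * units_au$me_per_amu
  omega <- sqrt(k / m_au)
  period_fs <- 2 * pi / omega * units_au$fs_per_atu
  dt <- period_fs / 100
  sys <- md_system_harmonic(k = k)
  g <- geometry("H", matrix(c(1, 0, 0), 1, 3))
  run <- run_md(sys, g, md_config(dt = dt, n_steps = 300, seed = 1),
                velocities = matrix(0, 1, 3))
  x <- vapply(run$frames, function(f) f$coords[1, 1], 0)
  # released from rest at the turning point: the first minimum sits at T/2
  minima <- which(diff(sign(diff(x))) == 2) + 1
  measured <- 2 * (minima[1] - 1) * dt
  expect_equal(measured, period_fs, tolerance = 0.01)
  # energy oscillation bounded (no drift), at the dt^2 level of the scheme
  et <- vapply(run$frames, function(f) f$energy_total, 0)
  expect_lt(diff(range(et)), 1e-3 * abs(et[1]) + 1e-4)
  fit <- lm(et ~ seq_along(et))
  expect_lt(abs(coef(fit)[2]) * length(et), 1e-4)
})

test_that("Bussi rescaling has the exact NVE limit and follows its formula", {
  expect_identical(bussi_rescale(0.01, 10, 300, Inf, 0.5), 1)

  set.seed(77)
  a <- bussi_rescale(0.008, 12, 300, 0.1, 0.5)
  set.seed(77)
  r1 <- rnorm(1)
  s <- rgamma(1, shape = 11 / 2, scale = 2)
  c_ <- exp(-0.5 / 100)
  kbar <- 0.5 * 12 * units_au$kboltz_hartree * 300
  ratio <- kbar / (12 * 0.008)
  a_ref <- sqrt(c_ + (1 - c_) * ratio * (r1^2 + s) +
                  2 * r1 * sqrt(c_ * (1 - c_) * ratio))
  expect_equal(a, a_ref, tolerance = 1e-14)
})

test_that("thermostatted harmonic dynamics samples the target temperature", {
  k <- 0.4
  sys <- md_system_harmonic(k = k)
  g <- geometry("H", matrix(c(1.2, 0, 0), 1, 3))
  run <- run_md(sys, g, md_config(dt = 1.0, n_steps = 20000,
                                  thermostat = "bussi", temperature = 300,
                                  tau = 0.05, seed = 4))
  kin <- vapply(run$frames, function(f) f$kinetic_energy, 0)
  kin <- kin[-(1:2000)]
  kbar <- 0.5 * 3 * units_au$kboltz_hartree * 300
  # standard error with a correlation-length correction
  neff <- length(kin) / 50
  se <- sd(kin) / sqrt(neff)
  expect_lt(abs(mean(kin) - kbar), 3 * se + 0.05 * kbar)
})

test_that("NVE dynamics on the gas-phase toy conserves the total energy", {
  toy <- get_toy_gas()
  sys <- md_system_ppp(toy$params, surface = "ground",
                       ground_mode = "restricted")
  run <- run_md(sys, toy$geometry,
                md_config(dt = 0.5, n_steps = 200, thermostat = "none",
                          temperature = 150, seed = 9))
  et <- vapply(run$frames, function(f) f$energy_total, 0)
  # drift: difference of endpoint means, plus no secular trend
  drift <- abs(mean(tail(et, 25)) - mean(head(et, 25)))
  expect_lt(drift, 1e-5)
  fit <- lm(et ~ seq_along(et))
  expect_lt(abs(coef(fit)[2]) * length(et), 1e-5)
})

test_that("checkpoint restart reproduces the uninterrupted trajectory", {
  toy <- get_toy_gas()
  sys <- md_system_ppp(toy$params, surface = "ground",
                       ground_mode = "restricted")
  cfg <- md_config(dt = 0.5, n_steps = 60, thermostat = "bussi",
                   temperature = 200, tau = 0.05, seed = 17)
  ck <- withr::local_tempfile(fileext = ".rds")
  full <- run_md(sys, toy$geometry, cfg)
  invisible(run_md(sys, toy$geometry, cfg, checkpoint_path = ck,
                   checkpoint_every = 40))
  resumed <- run_md(sys, toy$geometry, cfg, restart = ck)
  f_full <- full$frames[[61]]
  f_res <- resumed$frames[[length(resumed$frames)]]
  expect_identical(f_res$step_index, f_full$step_index)
  expect_equal(f_res$coords, f_full$coords, tolerance = 1e-12)
  expect_equal(f_res$velocities, f_full$velocities, tolerance = 1e-12)
  expect_equal(f_res$energy_total, f_full$energy_total, tolerance = 1e-12)
})

test_that("a sudden switch changes the forces (distinct surfaces)", {
  toy <- get_toy_gas()
  sys_g <- md_system_ppp(toy$params, surface = "ground",
                         ground_mode = "restricted")
  st_g <- elec_init(sys_g, toy$geometry)
  F_g <- compute_forces(sys_g, toy$geometry, st_g, md_config(n_steps = 1))
  sys_e <- md_system_ppp(toy$params, surface = "deltascf",
                         excitation = toy$excitation)
  st_e <- elec_init(sys_e, toy$geometry)
  F_e <- compute_forces(sys_e, toy$geometry, st_e, md_config(n_steps = 1))
  expect_gt(max(abs(F_e - F_g)), 1e-3)
})
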