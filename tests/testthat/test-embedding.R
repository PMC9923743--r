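
test_that("permanent fields match closed forms and the potential gradient", {
  # unit charge at origin, site 10 bohr up the z axis: E = q/r^2
  s <- embedding_sites(matrix(c(0, 0, 0), 1, 3), charge = 1,
                       alpha = 0, polarizable = FALSE, group = 1L)
  E <- multipole_field(s, matrix(c(0, 0, 10), 1, 3))
  expect_equal(as.vector(E), c(0, 0, 0.01), tolerance = 1e-12)

  # pure z dipole: on-axis field magnitude 2 mu / r^3 along z
  sd_ <- embedding_sites(matrix(c(0, 0, 0), 1, 3), charge = 0,
                         dipole = matrix(c(0, 0, 0.7), 1, 3),
                         alpha = 0, polarizable = FALSE, group = 1L)
  Ed <- multipole_field(sd_, matrix(c(0, 0, 4), 1, 3))
  expect_equal(as.vector(Ed), c(0, 0, 2 * 0.7 / 64), tolerance = 1e-12)

  # full multipole set against the numerical gradient of the potential
  sites <- make_random_sites(6)
  pt <- c(9, -3, 4)
  En <- oracle_num_grad(function(x) {
    -multipole_potential(sites, matrix(x, 1, 3))
  }, pt)
  Ea <- multipole_field(sites, matrix(pt, 1, 3))
  expect_equal(as.vector(Ea), En, tolerance = 1e-8)
})

test_that("induced dipoles solve the coupled linear system", {
  # single site: mu = alpha E
  s1 <- embedding_sites(matrix(0, 1, 3), alpha = 1.5,
                        polarizable = TRUE, group = 1L)
  ctx1 <- embedding_context(s1)
  st1 <- solve_induced_dipoles(ctx1, matrix(c(0, 0, 2), 1, 3))
  expect_equal(as.vector(st1$induced_dipoles), c(0, 0, 3), tolerance = 1e-12)

  # two distant sites: coupling negligible in the decoupled limit
  s2 <- embedding_sites(matrix(c(0, 0, 0, 1e4, 0, 0), 2, 3, byrow = TRUE),
                        alpha = c(2, 3), polarizable = c(TRUE, TRUE),
                        group = 1:2)
  ctx2 <- embedding_context(s2)
  Ef <- matrix(c(1, 0, 0, 0, 1, 0), 2, 3, byrow = TRUE)
  st2 <- solve_induced_dipoles(ctx2, Ef)
  expect_lt(max(abs(st2$induced_dipoles - Ef * c(2, 3))), 1e-10)

  # 20 random sites: CG matches the dense direct solve
  sites <- make_random_sites(20)
  ctx <- embedding_context(sites)
  E <- permanent_field(ctx)
  st <- solve_induced_dipoles(ctx, E)
  A <- diag(rep(1 / ctx$alpha_pol, each = 3)) - ctx$Tmat
  mu_dense <- matrix(solve(A, as.vector(t(E))), ncol = 3, byrow = TRUE)
  expect_lt(max(abs(st$induced_dipoles - mu_dense)), 1e-9)
})

test_that("polarization energy is -mu.E/2 and satisfies the variational identity", {
  st <- structure(list(induced_dipoles = matrix(c(0, 0, 3), 1, 3),
                       perm_field = matrix(c(0, 0, 2), 1, 3),
                       converged = TRUE), class = "polarization_state")
  expect_equal(polarization_energy(st), -3.0, tolerance = 1e-14)
  st0 <- structure(list(induced_dipoles = matrix(0, 1, 3),
                        perm_field = matrix(0, 1, 3), converged = TRUE),
                   class = "polarization_state")
  expect_equal(polarization_energy(st0), 0)
  st_bad <- st; st_bad$converged <- FALSE
  expect_error(polarization_energy(st_bad), "unconverged")

  sites <- make_random_sites(12, seed = 9)
  ctx <- embedding_context(sites)
  E <- permanent_field(ctx)
  sol <- solve_induced_dipoles(ctx, E)
  mu <- as.vector(t(sol$induced_dipoles))
  A <- diag(rep(1 / ctx$alpha_pol, each = 3)) - ctx$Tmat
  direct <- 0.5 * sum(mu * (A %*% mu)) - sum(mu * as.vector(t(E)))
  expect_equal(polarization_energy(sol), direct, tolerance = 1e-9)
  expect_lte(polarization_energy(sol), 0)
})

test_that("embedding response vanishes without sites and shifts PPP levels by 1/r", {
  m <- make_small_molecule("ppp_dimer")
  ints <- ppp_integrals(m$geometry, m$params)
  dens <- scf_solve(ints, 1, 1, mode = "restricted")$density

  # single -1 charge far away: each site level shifts by about +1/r
  r <- 60
  s <- embedding_sites(matrix(c(-r, 0, 0), 1, 3), charge = -1,
                       alpha = 0, polarizable = FALSE, group = 1L)
  ctx <- embedding_context(s)
  resp <- embedding_response(ctx, ints, dens)
  expect_equal(resp$v_embed[1, 1], 1 / r, tolerance = 1e-3)
  expect_gt(resp$v_embed[2, 2], 0)
})

test_that("Lowdin source charges conserve the net charge", {
  ints <- get_h2_ints()
  res <- scf_solve(ints, 1, 1, mode = "restricted")
  q <- qm_source_charges(res$density, ints)
  expect_equal(q, c(0, 0), tolerance = 1e-10)      # symmetry

  set.seed(13)
  for (k in 1:5) {
    A <- matrix(rnorm(4), 2, 2); da <- A %*% t(A)
    X <- lowdin_transform(ints$overlap)
    # normalize to trace 1 per spin in the AO metric
    da <- da / sum(da * ints$overlap)
    qk <- qm_source_charges(spin_density_pair(da, da), ints)
    expect_equal(sum(qk), 0, tolerance = 1e-10)
  }
})

test_that("environment coupling is variationally consistent (site-force check)", {
  # H2 plus one point charge: the analytic gradient of the total SCF energy
  # with respect to the charge position matches central differences
  m <- make_small_molecule("h2")
  ints <- gaussian_integrals(m$geometry, m$basis)
  pos0 <- c(2.5, 1.0, 4.0)
  energy_at <- function(x) {
    s <- embedding_sites(matrix(x, 1, 3), charge = -0.8, alpha = 0,
                         polarizable = FALSE, group = 1L)
    scf_solve(ints, 1, 1, mode = "restricted",
              embedding = embedding_context(s))$energy
  }
  gnum <- oracle_num_grad(energy_at, pos0)
  # analytic: Hellmann-Feynman at the converged density
  s <- embedding_sites(matrix(pos0, 1, 3), charge = -0.8, alpha = 0,
                       polarizable = FALSE, group = 1L)
  res <- scf_solve(ints, 1, 1, mode = "restricted",
                   embedding = embedding_context(s))
  dt <- res$density$d_alpha + res$density$d_beta
  G <- diabatmd:::attraction_matrix_grad(ints, pos0)
  gel <- vapply(G, function(M) -(-0.8) * sum(dt * M), 0)
  gnuc <- c(0, 0, 0)
  for (a in 1:2) {
    dr <- pos0 - m$geometry$coords[a, ]
    r3 <- sum(dr^2)^1.5
    gnuc <- gnuc + (-0.8) * m$geometry$charges[a] * (-dr / r3)
  }
  expect_equal(gel + gnuc, gnum, tolerance = 1e-6)
})

test_that("state-specific polarization: the CT environment response is stronger", {
  st <- get_toy_states()
  expect_lt(st$ct$e_pol, st$gs$e_pol)
  expect_lte(st$ct$e_pol, 0)
  expect_lte(st$gs$e_pol, 0)
})

test_that("frozen depolarized sites leave the polarization system exactly", {
  sites <- make_random_sites(12, seed = 15)
  far <- 9:12
  sites$alpha[far] <- 0
  sites$polarizable[far] <- FALSE
  sites$frozen[far] <- TRUE
  ctx <- embedding_context(sites)
  expect_identical(ctx$pol_idx, 1:8)
  E <- permanent_field(ctx)
  sol <- solve_induced_dipoles(ctx, E)
  # dense solve of the reduced 24x24 system with full permanent sources
  A <- diag(rep(1 / sites$alpha[1:8], each = 3)) - ctx$Tmat
  mu_dense <- matrix(solve(A, as.vector(t(E))), ncol = 3, byrow = TRUE)
  expect_lt(max(abs(sol$induced_dipoles - mu_dense)), 1e-9)
  expect_equal(nrow(sol$induced_dipoles), 8)
})

test_that("an unconverged polarization solve is an error, never silent", {
  sites <- make_random_sites(20, seed = 23)
  ctx <- embedding_context(sites, cg_tol = 1e-14)
  ctx$cg_max_iter <- 1
  expect_error(solve_induced_dipoles(ctx, permanent_field(ctx)),
               "did not converge")
})
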