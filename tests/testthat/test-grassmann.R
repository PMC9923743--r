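random_projector <- function(n, k, seed) {
  set.seed(seed)
  Q <- qr.Q(qr(matrix(rnorm(n * n), n, n)))
  list(c0 = Q[, seq_len(k), drop = FALSE], Q = Q)
}

test_that("the log map vanishes at the base point and measures principal angles", {
  rp <- random_projector(6, 2, 31)
  D0 <- rp$c0 %*% t(rp$c0)
  G0 <- grassmann_log(D0, rp$c0)
  expect_lt(max(abs(G0)), 1e-12)

  # rotate the occupied space by a known principal angle
  th <- 0.3
  rp2 <- random_projector(4, 2, 32)
  R <- diag(4)
  R[c(1, 3), c(1, 3)] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  C2 <- (rp2$Q %*% R)[, 1:2]
  G <- grassmann_log(C2 %*% t(C2), rp2$c0)
  expect_equal(max(svd(G)$d), th, tolerance = 1e-10)
  expect_lt(max(abs(t(rp2$c0) %*% G)), 1e-10)     # horizontality
})

test_that("log and exp are mutually inverse", {
  for (seed in 41:43) {
    rp <- random_projector(8, 3, seed)
    set.seed(seed + 100)
    R <- qr.Q(qr(diag(8) + 0.3 * matrix(rnorm(64), 8, 8)))
    C <- (R %*% rp$Q)[, 1:3]
    D <- C %*% t(C)
    G <- grassmann_log(D, rp$c0)
    expect_lt(max(abs(grassmann_exp(G, rp$c0) - D)), 1e-10)
  }
})

test_that("the exp map returns idempotent densities with exact trace", {
  rp <- random_projector(8, 3, 55)
  set.seed(56)
  for (k in 1:100) {
    M <- matrix(rnorm(8 * 3, sd = 0.4), 8, 3)
    G <- M - rp$c0 %*% (t(rp$c0) %*% M)      # horizontal tangent
    D <- grassmann_exp(G, rp$c0)
    expect_lt(max(abs(D %*% D - D)), 1e-12)
    expect_equal(sum(diag(D)), 3, tolerance = 1e-12)
  }
  expect_equal(grassmann_exp(matrix(0, 8, 3), rp$c0),
               rp$c0 %*% t(rp$c0), tolerance = 1e-14)
  expect_error(grassmann_exp(rp$c0, rp$c0), "horizontality")
})

test_that("reference too far from the occupied space is an error", {
  rp <- random_projector(4, 1, 61)
  c_perp <- rp$Q[, 2, drop = FALSE]
  expect_error(grassmann_log(c_perp %*% t(c_perp), rp$c0), "reference too far")
})

test_that("the Coulomb descriptor follows its closed form and symmetries", {
  g1 <- geometry("H", matrix(0, 1, 3) + c(1, 0, 0))
  expect_equal(coulomb_descriptor(g1), 0.5)

  g2 <- geometry(c("H", "H"), matrix(c(0, 0, 0, 1, 0, 0), 2, 3,
                                     byrow = TRUE))
  expect_equal(coulomb_descriptor(g2), c(0.5, 1, 0.5), tolerance = 1e-14)

  toyg <- get_toy_gas()$geometry
  d0 <- coulomb_descriptor(toyg)
  th <- 0.5
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  g3 <- geometry(toyg$symbols, toyg$coords %*% R + 2, charges = toyg$charges,
                 masses = toyg$masses)
  expect_equal(coulomb_descriptor(g3), d0, tolerance = 1e-12)
})

test_that("coefficient fitting reproduces exact linear combinations", {
  d1 <- c(1, 2, 3); d2 <- c(0.5, -1, 2)
  expect_equal(fit_coefficients(list(d1), d1), 1, tolerance = 1e-8)
  expect_equal(fit_coefficients(list(d1, d2), 0.3 * d1 + 0.7 * d2),
               c(0.3, 0.7), tolerance = 1e-6)
  # collinear history: the fit still reproduces the target in norm
  cf <- fit_coefficients(list(d1, 2 * d1), 3 * d1)
  resid <- 3 * d1 - cf[1] * d1 - cf[2] * 2 * d1
  expect_lt(sqrt(sum(resid^2)), 1e-8)
})

test_that("a stationary history reproduces the converged density", {
  m <- make_small_molecule("ppp_4site")
  ints <- ppp_integrals(m$geometry, m$params)
  res <- scf_solve(ints, 2, 2, mode = "restricted")
  h <- extrapolation_history(capacity = 6, overlap = ints$overlap)
  for (k in 1:3) history_push(h, res$density, m$geometry)
  guess <- extrapolate_guess(h, m$geometry)
  expect_lt(max(abs(guess$d_alpha - res$density$d_alpha)), 1e-10)
  res2 <- scf_solve(ints, 2, 2, guess = guess, mode = "restricted")
  expect_lte(res2$n_iterations, 2)
})

test_that("extrapolation beats the previous-density guess on a smooth path", {
  # densities along a smooth one-parameter geometry path, equal steps
  m <- make_small_molecule("ppp_4site")
  stretch <- function(s) {
    geometry(m$geometry$symbols, m$geometry$coords * (1 + s),
             charges = m$geometry$charges)
  }
  svals <- seq(0, 0.05, by = 0.01)
  h <- extrapolation_history(capacity = 6, overlap = diag(4))
  dens <- list()
  for (i in seq_along(svals)) {
    g <- stretch(svals[i])
    r <- scf_solve(ppp_integrals(g, m$params), 2, 2, mode = "restricted")
    dens[[i]] <- r$density
    if (i < length(svals)) history_push(h, r$density, g)
  }
  gtarget <- stretch(svals[length(svals)])
  guess <- extrapolate_guess(h, gtarget)
  dtrue <- dens[[length(svals)]]$d_alpha
  err_extra <- max(abs(guess$d_alpha - dtrue))
  err_prev <- max(abs(dens[[length(svals) - 1]]$d_alpha - dtrue))
  expect_lt(err_extra, err_prev / 10)
})

test_that("open-shell histories extrapolate both spins with correct traces", {
  st <- get_toy_states()
  toy <- st$toy
  h <- extrapolation_history(capacity = 6,
                             overlap = diag(st$ints$n_basis))
  # perturb the proton slightly to generate distinct history entries
  prev <- st$ct
  geomk <- toy$geometry
  for (k in 1:3) {
    geomk <- geometry(geomk$symbols,
                      geomk$coords + c(rep(0, 5), 0.01, rep(0, 12)),
                      charges = geomk$charges, masses = geomk$masses)
    ints <- ppp_integrals(geomk, toy$params)
    prev <- deltascf_solve(ints, ground = NULL, method = "imom",
                           embedding = st$ctx,
                           reference = prev$reference, guess = prev$density,
                           control = scf_control(tol_commutator = 1e-6,
                                                 max_cycles = 300))
    history_push(h, prev$density, geomk)
  }
  gnext <- geometry(geomk$symbols,
                    geomk$coords + c(rep(0, 5), 0.01, rep(0, 12)),
                    charges = geomk$charges, masses = geomk$masses)
  guess <- extrapolate_guess(h, gnext)
  expect_false(isTRUE(all.equal(guess$d_alpha, guess$d_beta)))
  expect_equal(sum(diag(guess$d_alpha)), 3, tolerance = 1e-12)
  expect_equal(sum(diag(guess$d_beta)), 3, tolerance = 1e-12)
  Da <- guess$d_alpha
  expect_lt(max(abs(Da %*% Da - Da)), 1e-12)
})

test_that("identical histories give bit-identical guesses", {
  m <- make_small_molecule("ppp_4site")
  ints <- ppp_integrals(m$geometry, m$params)
  res <- scf_solve(ints, 2, 2, mode = "restricted")
  build <- function() {
    h <- extrapolation_history(capacity = 6, overlap = ints$overlap)
    for (k in 1:3) history_push(h, res$density, m$geometry)
    extrapolate_guess(h, m$geometry)
  }
  expect_identical(build()$d_alpha, build()$d_alpha)
})
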