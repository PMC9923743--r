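#' @title AMOEBA-style polarizable environment
#' @name polarizable_embedding
#' @description
#' Permanent-multipole electrostatics (charges, dipoles, traceless Cartesian
#' quadrupoles), Thole-damped induced point dipoles solved by a diagonally
#' preconditioned conjugate-gradient iteration, and mutual, state-specific
#' coupling with the QM density.  The QM density polarizes the environment
#' through its Lowdin atomic charges; the environment acts back on the
#' electrons through exact charge-type integrals (Gaussian provider) or
#' site potentials (PPP provider).  Because the induced dipoles are at
#' their variational optimum inside every Fock build, the excited-state
#' response is obtained self-consistently and is specific to the state
#' being converged.
NULL

# potential of all permanent multipoles at points (m x 3): no exclusions
multipole_potential <- function(sites, points) {
  np <- nrow(points)
  ns <- nrow(sites$positions)
  phi <- numeric(np)
  for (s in seq_len(ns)) {
    dr <- sweep(points, 2, sites$positions[s, ])
    r2 <- rowSums(dr^2)
    r <- sqrt(r2)
    phi <- phi + sites$charge[s] / r +
      (dr %*% sites$dipole[s, ])[, 1] / r^3 +
      1.5 * rowSums((dr %*% sites$quadrupole[s, , ]) * dr) / r^5
  }
  phi
}

# field (-grad phi) of permanent multipoles at points; optionally exclude
# sites sharing a group id with `point_groups`
multipole_field <- function(sites, points, point_groups = NULL) {
  np <- nrow(points)
  E <- matrix(0, np, 3)
  for (s in seq_len(nrow(sites$positions))) {
    dr <- sweep(points, 2, sites$positions[s, ])
    r2 <- rowSums(dr^2)
    r <- sqrt(r2)
    sel <- rep(TRUE, np)
    if (!is.null(point_groups)) sel <- point_groups != sites$group[s]
    if (!any(sel)) next
    q <- sites$charge[s]
    mu <- sites$dipole[s, ]
    Q <- sites$quadrupole[s, , ]
    Eq <- q * dr / r^3
    mudr <- (dr %*% mu)[, 1]
    Emu <- 3 * mudr * dr / r^5 - matrix(mu, np, 3, byrow = TRUE) / r^3
    Qdr <- dr %*% Q
    drQdr <- rowSums(Qdr * dr)
    EQ <- -3 * Qdr / r^5 + 7.5 * drQdr * dr / r^7
    Etot <- Eq + Emu + EQ
    E[sel, ] <- E[sel, ] + Etot[sel, ]
  }
  E
}

# field at points from point charges q at positions pos
charge_field <- function(q, pos, points) {
  E <- matrix(0, nrow(points), 3)
  for (a in seq_along(q)) {
    if (q[a] == 0) next
    dr <- sweep(points, 2, pos[a, ])
    r3 <- rowSums(dr^2)^1.5
    E <- E + q[a] * dr / r3
  }
  E
}

# potential at points from point dipoles mu (k x 3) at positions pos
dipole_potential <- function(mu, pos, points) {
  phi <- numeric(nrow(points))
  for (p in seq_len(nrow(pos))) {
    dr <- sweep(points, 2, pos[p, ])
    r3 <- rowSums(dr^2)^1.5
    phi <- phi + (dr %*% mu[p, ])[, 1] / r3
  }
  phi
}

# field at points from point dipoles (undamped)
dipole_field <- function(mu, pos, points) {
  E <- matrix(0, nrow(points), 3)
  for (p in seq_len(nrow(pos))) {
    dr <- sweep(points, 2, pos[p, ])
    r2 <- rowSums(dr^2)
    r <- sqrt(r2)
    mudr <- (dr %*% mu[p, ])[, 1]
    E <- E + 3 * mudr * dr / r^5 - matrix(mu[p, ], nrow(points), 3,
                                          byrow = TRUE) / r^3
  }
  E
}

# Thole-damped dipole-dipole interaction matrix over polarizable sites
# (3m x 3m); exponential charge-smearing damping with global factor a and
# effective distance u = r / (alpha_i alpha_j)^(1/6); same-group pairs are
# excluded from mutual induction
.thole_tensor <- function(sites, pol_idx, a) {
  m <- length(pol_idx)
  T <- matrix(0, 3 * m, 3 * m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i == j) next
      si <- pol_idx[i]; sj <- pol_idx[j]
      if (sites$group[si] == sites$group[sj]) next
      dr <- sites$positions[si, ] - sites$positions[sj, ]
      r <- sqrt(sum(dr^2))
      u <- r / (sites$alpha[si] * sites$alpha[sj])^(1 / 6)
      au3 <- a * u^3
      l3 <- 1 - exp(-au3)
      l5 <- 1 - (1 + au3) * exp(-au3)
      Tij <- 3 * l5 * outer(dr, dr) / r^5 - l3 * diag(3) / r^3
      T[(3 * i - 2):(3 * i), (3 * j - 2):(3 * j)] <- Tij
    }
  }
  T
}

#' Create an embedding context
#'
#' Precomputes everything about the environment that does not depend on the
#' QM geometry or density: the polarizable-site list, the Thole-damped
#' mutual-induction matrix and the permanent fields at the polarizable
#' sites (same-group contributions excluded).
#'
#' @param sites an `embedding_sites` object
#' @param thole_a global Thole damping factor (default 0.39)
#' @param cg_tol conjugate-gradient residual tolerance
#' @param cg_max_iter maximum CG iterations
#' @return an environment of class `embedding_context`
#' @export
embedding_context <- function(sites, thole_a = 0.39, cg_tol = 1e-10,
                              cg_max_iter = 200) {
  ctx <- new.env(parent = emptyenv())
  ctx$sites <- sites
  ctx$thole_a <- thole_a
  ctx$cg_tol <- cg_tol
  ctx$cg_max_iter <- cg_max_iter
  ctx$pol_idx <- which(sites$polarizable & sites$alpha > 0)
  m <- length(ctx$pol_idx)
  if (m > 0) {
    ctx$Tmat <- .thole_tensor(sites, ctx$pol_idx, thole_a)
    ctx$alpha_pol <- sites$alpha[ctx$pol_idx]
    pol_pos <- sites$positions[ctx$pol_idx, , drop = FALSE]
    ctx$pol_pos <- pol_pos
    ctx$field_perm_sites <- multipole_field(
      sites, pol_pos, point_groups = sites$group[ctx$pol_idx])
  } else {
    ctx$pol_pos <- matrix(0, 0, 3)
    ctx$field_perm_sites <- matrix(0, 0, 3)
  }
  ctx$cache_key <- NULL
  class(ctx) <- c("embedding_context", "environment")
  ctx
}

#' Permanent field at the polarizable sites
#'
#' Field from the environment's own permanent multipoles (same-group
#' contributions excluded) plus the field of the QM point charges.
#'
#' @param ctx an `embedding_context`
#' @param qm_charges per-atom QM charges (e), or NULL
#' @param qm_positions n x 3 atom positions (bohr)
#' @return m x 3 field matrix at the polarizable sites (a.u.)
#' @export
permanent_field <- function(ctx, qm_charges = NULL, qm_positions = NULL) {
  E <- ctx$field_perm_sites
  if (!is.null(qm_charges) && length(ctx$pol_idx) > 0) {
    E <- E + charge_field(qm_charges, qm_positions, ctx$pol_pos)
  }
  E
}

#' Solve the induced-point-dipole equations
#'
#' Solves `(alpha^-1 - T) mu = E_perm` by conjugate gradient with the
#' diagonal (alpha) preconditioner; `T` is the Thole-damped mutual
#' interaction.  Non-convergence signals a polarization catastrophe and is
#' an error, never silent.
#'
#' @param ctx an `embedding_context`
#' @param field m x 3 permanent field at the polarizable sites
#' @param mu_warm optional warm-start dipoles (m x 3)
#' @return list of class `polarization_state`: `induced_dipoles` (m x 3),
#'   `perm_field`, `converged`, `residual_norm`, `n_iterations`
#' @export
solve_induced_dipoles <- function(ctx, field, mu_warm = NULL) {
  m <- length(ctx$pol_idx)
  if (m == 0) {
    return(structure(list(induced_dipoles = matrix(0, 0, 3),
                          perm_field = field, converged = TRUE,
                          residual_norm = 0, n_iterations = 0),
                     class = "polarization_state"))
  }
  b <- as.vector(t(field))              # (x1,y1,z1,x2,...)
  ainv <- rep(1 / ctx$alpha_pol, each = 3)
  Amul <- function(x) ainv * x - ctx$Tmat %*% x
  x <- if (is.null(mu_warm)) numeric(3 * m) else as.vector(t(mu_warm))
  r <- b - Amul(x)
  z <- r / ainv
  p <- z
  rz <- sum(r * z)
  conv <- FALSE; it <- 0
  for (it in seq_len(ctx$cg_max_iter)) {
    if (sqrt(sum(r^2)) < ctx$cg_tol) { conv <- TRUE; break }
    Ap <- Amul(p)
    a_ <- rz / sum(p * Ap)
    x <- x + a_ * p
    r <- r - a_ * Ap
    z <- r / ainv
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  if (!conv && sqrt(sum(r^2)) >= ctx$cg_tol) {
    stop("solve_induced_dipoles: CG did not converge in ",
         ctx$cg_max_iter, " iterations (residual ",
         format(sqrt(sum(r^2))), "); polarization catastrophe?")
  }
  structure(list(induced_dipoles = matrix(x, ncol = 3, byrow = TRUE),
                 perm_field = field, converged = TRUE,
                 residual_norm = sqrt(sum(r^2)), n_iterations = it),
            class = "polarization_state")
}

#' Polarization energy of a converged induced-dipole state
#'
#' `E_pol = -1/2 sum_i mu_i . E_perm,i`; non-positive whenever the field
#' arises from permanent and QM sources only.
#'
#' @param state a `polarization_state`
#' @return energy in hartree
#' @export
polarization_energy <- function(state) {
  if (!state$converged) stop("polarization_energy: unconverged state")
  -0.5 * sum(state$induced_dipoles * state$perm_field)
}

#' Lowdin point charges of the QM density
#'
#' Per-atom net charges (core charge minus Lowdin population); these are
#' the QM sources seen by the polarizable environment.  Charges sum to the
#' net QM charge.
#'
#' @param density `spin_density_pair` (AO)
#' @param integrals `integral_set`
#' @return per-atom charges (e)
#' @export
qm_source_charges <- function(density, integrals) {
  geom <- integrals$provider_data$geom
  zc <- if (integrals$provider == "ppp") {
    integrals$provider_data$core_charges
  } else {
    geom$charges
  }
  zc - lowdin_populations(density, integrals)
}

# per-geometry cached permanent-electrostatics pieces
.embed_geom_cache <- function(ctx, integrals) {
  geom <- integrals$provider_data$geom
  key <- c(geom$coords)
  if (!is.null(ctx$cache_key) && length(ctx$cache_key) == length(key) &&
      all(ctx$cache_key == key)) {
    return(invisible(NULL))
  }
  sites <- ctx$sites
  pos <- geom$coords
  ctx$phi_perm_atoms <- multipole_potential(sites, pos)
  if (integrals$provider == "gaussian") {
    n <- integrals$n_basis
    v <- matrix(0, n, n)
    for (s in seq_len(nrow(sites$positions))) {
      if (sites$charge[s] != 0) {
        v <- v - sites$charge[s] *
          attraction_matrix(integrals, sites$positions[s, ])
      }
    }
    ctx$v_mono <- v
    # dipole+quadrupole potential at atoms, coupled via Lowdin charges
    mono_only <- sites
    mono_only$dipole <- 0 * mono_only$dipole
    mono_only$quadrupole <- 0 * mono_only$quadrupole
    ctx$phi_dq_atoms <- ctx$phi_perm_atoms - multipole_potential(mono_only, pos)
    ctx$Shalf <- .sqrtm(integrals$overlap)
  } else {
    ctx$v_mono <- NULL
    ctx$phi_dq_atoms <- NULL
  }
  ctx$cache_key <- key
  invisible(NULL)
}

# one-electron operator coupling a per-atom potential through Lowdin charges
.lowdin_potential_operator <- function(phi_atoms, integrals, Shalf = NULL) {
  phib <- phi_atoms[integrals$basis_centers]
  if (integrals$provider == "ppp") return(diag(-phib, nrow = length(phib)))
  -Shalf %*% (diag(phib, nrow = length(phib)) %*% Shalf)
}

#' Environment response to a QM density
#'
#' The full mutual-coupling step used inside every Fock build: Lowdin
#' source charges, permanent + QM fields at the polarizable sites, induced
#' dipoles (warm-startable conjugate gradient), and the resulting
#' one-electron embedding operator and energy terms.
#'
#' @param ctx an `embedding_context`
#' @param integrals `integral_set` (carries the geometry)
#' @param density `spin_density_pair` (AO basis)
#' @param mu_warm optional warm-start induced dipoles
#' @return list with `v_embed` (one-electron operator), `e_fixed_elec`
#'   (QM charge distribution vs permanent multipoles, hartree), `e_pol`
#'   (polarization energy), `mu` (induced dipoles), `state`
#'   (`polarization_state`), `q_src` (Lowdin charges)
#' @export
embedding_response <- function(ctx, integrals, density, mu_warm = NULL) {
  .embed_geom_cache(ctx, integrals)
  geom <- integrals$provider_data$geom
  pos <- geom$coords
  q <- qm_source_charges(density, integrals)
  E_src <- permanent_field(ctx, q, pos)
  state <- solve_induced_dipoles(ctx, E_src, mu_warm = mu_warm)
  mu <- state$induced_dipoles
  e_pol <- if (length(ctx$pol_idx) > 0) polarization_energy(state) else 0
  phi_ind <- if (length(ctx$pol_idx) > 0) {
    dipole_potential(mu, ctx$pol_pos, pos)
  } else {
    numeric(nrow(pos))
  }
  zc <- if (integrals$provider == "ppp") {
    integrals$provider_data$core_charges
  } else {
    geom$charges
  }
  if (integrals$provider == "ppp") {
    v_perm <- .lowdin_potential_operator(ctx$phi_perm_atoms, integrals)
    v_ind <- .lowdin_potential_operator(phi_ind, integrals)
  } else {
    v_perm <- ctx$v_mono +
      .lowdin_potential_operator(ctx$phi_dq_atoms, integrals, ctx$Shalf)
    v_ind <- .lowdin_potential_operator(phi_ind, integrals, ctx$Shalf)
  }
  dt <- density$d_alpha + density$d_beta
  e_fixed <- sum(dt * v_perm) + sum(zc * ctx$phi_perm_atoms)
  list(v_embed = v_perm + v_ind, e_fixed_elec = e_fixed, e_pol = e_pol,
       mu = mu, state = state, q_src = q)
}

# total environment field (permanent multipoles + induced dipoles) at
# arbitrary points; used by the analytic force evaluation
env_total_field <- function(ctx, points, mu) {
  E <- multipole_field(ctx$sites, points)
  if (!is.null(mu) && nrow(ctx$pol_pos) > 0) {
    E <- E + dipole_field(mu, ctx$pol_pos, points)
  }
  E
}
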