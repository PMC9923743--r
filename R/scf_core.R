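#' @title Ground-state SCF engine
#' @name scf_core
#' @description
#' Restricted and unrestricted Hartree-Fock with DIIS over either integral
#' provider, optionally coupled self-consistently to the polarizable
#' environment.  The same engine, with pluggable occupation selection and
#' Fock-shift hooks, drives the excited-state (Delta-SCF) solvers.
NULL

#' Spin-resolved density-matrix pair
#'
#' @param d_alpha,d_beta n x n symmetric density matrices
#' @param basis `"AO"` or `"orthonormal"`
#' @return object of class `spin_density_pair`
#' @export
spin_density_pair <- function(d_alpha, d_beta, basis = "AO") {
  stopifnot(basis %in% c("AO", "orthonormal"))
  if (max(abs(d_alpha - t(d_alpha))) > 1e-12 ||
      max(abs(d_beta - t(d_beta))) > 1e-12) {
    stop("spin_density_pair: density not symmetric")
  }
  structure(list(d_alpha = d_alpha, d_beta = d_beta, basis = basis),
            class = "spin_density_pair")
}

#' Validate density-matrix traces against electron counts
#' @param density a `spin_density_pair`
#' @param overlap AO overlap (needed in AO basis)
#' @param n_alpha,n_beta electron counts
#' @param tol tolerance on the traces
#' @return TRUE invisibly; stops on violation
#' @export
check_density_traces <- function(density, overlap, n_alpha, n_beta,
                                 tol = 1e-10) {
  tr <- function(D) if (density$basis == "AO") sum(D * overlap) else sum(diag(D))
  if (abs(tr(density$d_alpha) - n_alpha) > tol ||
      abs(tr(density$d_beta) - n_beta) > tol) {
    stop("spin_density_pair: trace does not match electron count")
  }
  invisible(TRUE)
}

#' Lowdin symmetric orthonormalization
#'
#' @param overlap symmetric positive-definite matrix
#' @return X = S^(-1/2) such that t(X) S X = I
#' @export
lowdin_transform <- function(overlap) {
  e <- eigen(overlap, symmetric = TRUE)
  if (min(e$values) < 1e-10) {
    stop("lowdin_transform: near-linear-dependent overlap (min eigenvalue ",
         format(min(e$values)), ")")
  }
  e$vectors %*% (t(e$vectors) / sqrt(e$values))
}

#' Build the unrestricted Fock matrices
#'
#' `F_sigma = hcore + J[D_alpha + D_beta] - K[D_sigma] + v_embed`.
#'
#' @param density a `spin_density_pair` in the AO basis
#' @param integrals an `integral_set`
#' @param v_embed one-electron embedding operator (matrix) or 0
#' @return list `(f_alpha, f_beta)`
#' @export
build_fock <- function(density, integrals, v_embed = 0) {
  n <- integrals$n_basis
  if (nrow(density$d_alpha) != n) stop("build_fock: dimension mismatch")
  dt <- density$d_alpha + density$d_beta
  J <- matrix(integrals$eriJ %*% as.vector(dt), n, n)
  Ka <- matrix(integrals$eriK %*% as.vector(density$d_alpha), n, n)
  Kb <- matrix(integrals$eriK %*% as.vector(density$d_beta), n, n)
  fa <- integrals$hcore + J - Ka + v_embed
  fb <- integrals$hcore + J - Kb + v_embed
  list(f_alpha = (fa + t(fa)) / 2, f_beta = (fb + t(fb)) / 2)
}

# bare (no-embedding) electronic + nuclear energy of a density
.uhf_energy_bare <- function(density, integrals) {
  n <- integrals$n_basis
  da <- density$d_alpha; db <- density$d_beta
  dt <- da + db
  J <- matrix(integrals$eriJ %*% as.vector(dt), n, n)
  Ka <- matrix(integrals$eriK %*% as.vector(da), n, n)
  Kb <- matrix(integrals$eriK %*% as.vector(db), n, n)
  e <- sum(dt * integrals$hcore) +
    0.5 * (sum(da * (J - Ka)) + sum(db * (J - Kb)))
  e + integrals$nuclear_repulsion
}

#' Total energy of a given spin density (with optional embedding)
#'
#' Direct evaluation of the implemented total-energy expression at a fixed
#' density: QM determinant energy plus, when an embedding context is given,
#' the fixed electrostatic and self-consistent polarization terms.
#'
#' @param density `spin_density_pair` (AO basis)
#' @param integrals `integral_set`
#' @param embedding optional embedding context from [embedding_context()]
#' @return list `(energy, e_qm, e_fixed_elec, e_pol)`
#' @export
total_energy <- function(density, integrals, embedding = NULL) {
  e_qm <- .uhf_energy_bare(density, integrals)
  if (is.null(embedding)) {
    return(list(energy = e_qm, e_qm = e_qm, e_fixed_elec = 0, e_pol = 0))
  }
  resp <- embedding_response(embedding, integrals, density)
  list(energy = e_qm + resp$e_fixed_elec + resp$e_pol, e_qm = e_qm,
       e_fixed_elec = resp$e_fixed_elec, e_pol = resp$e_pol)
}

#' DIIS extrapolation of the Fock matrices
#'
#' Pulay commutator-error DIIS with coefficients constrained to sum to one.
#' A numerically singular B matrix degrades gracefully to the latest Fock.
#'
#' @param fock_history list of `(f_alpha, f_beta)` pairs
#' @param error_history list of error vectors (orthonormal-basis FDS-SDF,
#'   both spins concatenated)
#' @return extrapolated `(f_alpha, f_beta)` pair
#' @export
diis_extrapolate <- function(fock_history, error_history) {
  m <- length(fock_history)
  stopifnot(m >= 1, length(error_history) == m)
  if (m == 1) return(fock_history[[1]])
  B <- matrix(0, m + 1, m + 1)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    B[i, j] <- sum(error_history[[i]] * error_history[[j]])
  }
  B[m + 1, seq_len(m)] <- -1
  B[seq_len(m), m + 1] <- -1
  rhs <- c(rep(0, m), -1)
  c_ <- tryCatch(solve(B, rhs)[seq_len(m)], error = function(e) NULL)
  if (is.null(c_) || any(!is.finite(c_))) return(fock_history[[m]])
  fa <- 0; fb <- 0
  for (i in seq_len(m)) {
    fa <- fa + c_[i] * fock_history[[i]]$f_alpha
    fb <- fb + c_[i] * fock_history[[i]]$f_beta
  }
  list(f_alpha = fa, f_beta = fb)
}

#' SCF control settings
#' @param tol_commutator convergence threshold on max |FDS - SDF|
#'   (orthonormal basis)
#' @param tol_energy convergence threshold on the energy change (hartree)
#' @param max_cycles maximum SCF cycles
#' @param diis_depth DIIS history depth
#' @param guess_mix_angle HOMO/LUMO mixing angle (radians) applied to the
#'   alpha guess orbitals, for symmetry breaking in UHF
#' @param damping static density mixing `D <- (1 - damping) D_new +
#'   damping D_old` (0 = off); a convergence aid for oscillating cases
#' @return named list
#' @export
scf_control <- function(tol_commutator = 1e-8, tol_energy = 1e-10,
                        max_cycles = 200, diis_depth = 8,
                        guess_mix_angle = 0, damping = 0) {
  list(tol_commutator = tol_commutator, tol_energy = tol_energy,
       max_cycles = max_cycles, diis_depth = diis_depth,
       guess_mix_angle = guess_mix_angle, damping = damping)
}

# density from occupied columns
.density_from_occ <- function(C, occ) {
  Co <- C[, occ, drop = FALSE]
  Co %*% t(Co)
}

#' Solve the SCF equations
#'
#' Ground-state restricted/unrestricted Hartree-Fock; with the `occ_select`
#' or `fock_shift` hooks it also serves as the Delta-SCF engine (non-Aufbau
#' occupation selection or level-shifted Aufbau).  When an embedding context
#' is present the induced dipoles are re-converged inside every Fock build
#' (warm-started from the previous cycle) and the returned energy includes
#' the fixed-electrostatic and polarization terms.
#'
#' @param integrals an `integral_set`
#' @param n_alpha,n_beta electron counts
#' @param guess `"core"` for a diagonalized-hcore guess, or a
#'   `spin_density_pair` in the AO basis
#' @param mode `"restricted"` or `"unrestricted"`
#' @param embedding optional embedding context ([embedding_context()])
#' @param control list from [scf_control()]
#' @param occ_select optional `function(C, eps, spin)` returning the
#'   occupied column indices (e.g. iMOM); default Aufbau
#' @param fock_shift optional `function(F, spin, c_occ)` applied to the
#'   Fock matrix before diagonalization (e.g. STEP level shift); `c_occ`
#'   holds the current iterate's occupied orbital coefficients
#' @return object of class `scf_result`: fields `energy`, `e_qm`,
#'   `e_fixed_elec`, `e_pol`, `orbitals` (`c_alpha`, `c_beta`, `eps_alpha`,
#'   `eps_beta`, `occ_alpha`, `occ_beta`), `density` (AO), `converged`,
#'   `n_iterations`, `commutator_norm`, `mu_induced`
#' @export
scf_solve <- function(integrals, n_alpha, n_beta, guess = "core",
                      mode = c("unrestricted", "restricted"),
                      embedding = NULL, control = scf_control(),
                      occ_select = NULL, fock_shift = NULL) {
  mode <- match.arg(mode)
  if (mode == "restricted" && n_alpha != n_beta) {
    stop("scf_solve: restricted mode requires n_alpha == n_beta")
  }
  n <- integrals$n_basis
  S <- integrals$overlap
  X <- lowdin_transform(S)
  aufbau <- function(C, eps, spin) seq_len(if (spin == "alpha") n_alpha else n_beta)
  if (is.null(occ_select)) occ_select <- aufbau

  # ---- initial density -----------------------------------------------
  # eigen() sorts decreasing; orbitals must come lowest-first
  eig_asc <- function(M) {
    e <- eigen((M + t(M)) / 2, symmetric = TRUE)
    ord <- order(e$values)
    list(values = e$values[ord], vectors = e$vectors[, ord, drop = FALSE])
  }

  if (identical(guess, "core")) {
    e0 <- eig_asc(t(X) %*% integrals$hcore %*% X)
    C0 <- X %*% e0$vectors
    if (control$guess_mix_angle != 0 && n_alpha < n) {
      th <- control$guess_mix_angle
      h <- C0[, n_alpha]; l <- C0[, n_alpha + 1]
      Ca0 <- C0
      Ca0[, n_alpha] <- cos(th) * h + sin(th) * l
      Ca0[, n_alpha + 1] <- -sin(th) * h + cos(th) * l
    } else {
      Ca0 <- C0
    }
    da <- .density_from_occ(Ca0, seq_len(n_alpha))
    db <- .density_from_occ(C0, seq_len(n_beta))
    if (mode == "restricted") db <- da
  } else {
    stopifnot(inherits(guess, "spin_density_pair"))
    if (guess$basis != "AO") stop("scf_solve: guess must be in the AO basis")
    da <- guess$d_alpha; db <- guess$d_beta
  }

  # current occupied orbitals (for level-shift hooks): from the guess density
  occ_from_density <- function(D, nocc) {
    Shalf <- .sqrtm(S)
    Don <- Shalf %*% D %*% Shalf
    e <- eigen((Don + t(Don)) / 2, symmetric = TRUE)
    X %*% e$vectors[, seq_len(nocc), drop = FALSE]
  }
  occ_orb_a <- if (!is.null(fock_shift)) occ_from_density(da, n_alpha) else NULL
  occ_orb_b <- if (!is.null(fock_shift)) occ_from_density(db, n_beta) else NULL

  fock_hist <- list(); err_hist <- list()
  e_old <- Inf; conv <- FALSE; comm <- Inf
  mu_warm <- NULL
  e_tot <- NA_real_; e_fixed <- 0; e_pol <- 0; e_qm <- NA_real_
  Ca <- Cb <- NULL; epsa <- epsb <- NULL; occa <- occb <- NULL
  iter <- 0
  # best iterate seen: near-saddle excited states can touch the
  # convergence window and then escape along the unstable mode; the best
  # stationary iterate is the physical answer
  best <- list(comm = Inf)

  for (iter in seq_len(control$max_cycles)) {
    dens <- spin_density_pair(da, db)
    v_embed <- 0
    if (!is.null(embedding)) {
      resp <- embedding_response(embedding, integrals, dens,
                                 mu_warm = mu_warm)
      v_embed <- resp$v_embed
      e_fixed <- resp$e_fixed_elec
      e_pol <- resp$e_pol
      mu_warm <- resp$mu
    }
    fk <- build_fock(dens, integrals, v_embed)
    e_qm <- .uhf_energy_bare(dens, integrals)
    e_tot <- e_qm + e_fixed + e_pol

    err_a <- t(X) %*% (fk$f_alpha %*% da %*% S - S %*% da %*% fk$f_alpha) %*% X
    err_b <- t(X) %*% (fk$f_beta %*% db %*% S - S %*% db %*% fk$f_beta) %*% X
    comm <- max(abs(err_a), abs(err_b))
    de <- e_tot - e_old
    log_line("debug", sprintf("SCF cycle %d  E=%.12f  dE=%.3e  |[F,D]|=%.3e",
                              iter, e_tot, de, comm))
    if (iter > 1 && comm < best$comm) {
      best <- list(comm = comm, da = da, db = db, Ca = Ca, Cb = Cb,
                   epsa = epsa, epsb = epsb, occa = occa, occb = occb,
                   e_tot = e_tot, e_qm = e_qm, e_fixed = e_fixed,
                   e_pol = e_pol, mu = mu_warm)
    }
    if (comm < control$tol_commutator && abs(de) < control$tol_energy &&
        iter > 1) {
      conv <- TRUE
      break
    }
    e_old <- e_tot

    fock_hist <- c(fock_hist, list(fk))
    err_hist <- c(err_hist, list(c(err_a, err_b)))
    if (length(fock_hist) > max(control$diis_depth, 1)) {
      fock_hist <- fock_hist[-1]; err_hist <- err_hist[-1]
    }
    fk_use <- if (iter >= 2 && control$diis_depth >= 1) {
      diis_extrapolate(fock_hist, err_hist)
    } else {
      fk
    }
    if (!is.null(fock_shift)) {
      fk_use <- list(f_alpha = fock_shift(fk_use$f_alpha, "alpha", occ_orb_a),
                     f_beta = fock_shift(fk_use$f_beta, "beta", occ_orb_b))
    }

    solve_spin <- function(F) {
      e <- eig_asc(t(X) %*% F %*% X)
      list(C = X %*% e$vectors, eps = e$values)
    }
    da_old <- da; db_old <- db
    sa <- solve_spin(fk_use$f_alpha)
    occa <- sort(occ_select(sa$C, sa$eps, "alpha"))
    da <- .density_from_occ(sa$C, occa)
    Ca <- sa$C; epsa <- sa$eps
    if (!is.null(fock_shift)) occ_orb_a <- Ca[, occa, drop = FALSE]
    if (mode == "restricted") {
      Cb <- Ca; epsb <- epsa; occb <- occa; db <- da
      if (!is.null(fock_shift)) occ_orb_b <- occ_orb_a
    } else {
      sb <- solve_spin(fk_use$f_beta)
      occb <- sort(occ_select(sb$C, sb$eps, "beta"))
      db <- .density_from_occ(sb$C, occb)
      Cb <- sb$C; epsb <- sb$eps
      if (!is.null(fock_shift)) occ_orb_b <- Cb[, occb, drop = FALSE]
    }
    if (control$damping > 0) {
      b <- control$damping
      da <- (1 - b) * da + b * da_old
      db <- (1 - b) * db + b * db_old
    }
  }
  if (!conv && is.finite(best$comm) && best$comm < comm) {
    # the iteration escaped after its closest approach; report the best
    # iterate (flagged converged only if it met the threshold)
    da <- best$da; db <- best$db; Ca <- best$Ca; Cb <- best$Cb
    epsa <- best$epsa; epsb <- best$epsb; occa <- best$occa; occb <- best$occb
    e_tot <- best$e_tot; e_qm <- best$e_qm; e_fixed <- best$e_fixed
    e_pol <- best$e_pol; mu_warm <- best$mu
    comm <- best$comm
    conv <- comm < control$tol_commutator
  }
  if (!conv) {
    log_line("warn", sprintf("SCF did not converge in %d cycles (|[F,D]|=%.2e)",
                             control$max_cycles, comm))
  }
  structure(list(
    energy = e_tot, e_qm = e_qm, e_fixed_elec = e_fixed, e_pol = e_pol,
    orbitals = list(c_alpha = Ca, c_beta = Cb, eps_alpha = epsa,
                    eps_beta = epsb, occ_alpha = occa, occ_beta = occb),
    density = spin_density_pair(da, db),
    converged = conv, n_iterations = iter, commutator_norm = comm,
    mu_induced = mu_warm, n_alpha = n_alpha, n_beta = n_beta,
    mode = mode), class = "scf_result")
}

#' @export
print.scf_result <- function(x, ...) {
  cat(sprintf("<scf_result: E = %.10f hartree, %s in %d cycles, |[F,D]| = %.2e>\n",
              x$energy, if (x$converged) "converged" else "NOT converged",
              x$n_iterations, x$commutator_norm))
  invisible(x)
}

#' Expectation value of S^2 for an unrestricted determinant
#'
#' @param result an `scf_result`
#' @param overlap the AO overlap matrix
#' @return `<S^2>` of the single determinant
#' @export
determinant_s2 <- function(result, overlap) {
  oa <- result$orbitals
  Ca <- oa$c_alpha[, oa$occ_alpha, drop = FALSE]
  Cb <- oa$c_beta[, oa$occ_beta, drop = FALSE]
  na <- length(oa$occ_alpha); nb <- length(oa$occ_beta)
  sz <- (na - nb) / 2
  sab <- t(Ca) %*% overlap %*% Cb
  sz * (sz + 1) + nb - sum(sab^2)
}

#' Lowdin atomic populations of a density
#'
#' @param density `spin_density_pair` (AO)
#' @param integrals `integral_set`
#' @return per-atom electron populations (length = number of atoms,
#'   zero for atoms without basis functions)
#' @export
lowdin_populations <- function(density, integrals) {
  Sh <- .sqrtm(integrals$overlap)
  P <- Sh %*% (density$d_alpha + density$d_beta) %*% Sh
  geom <- integrals$provider_data$geom
  na <- length(geom$symbols)
  pops <- numeric(na)
  d <- diag(P)
  for (b in seq_along(integrals$basis_centers)) {
    a <- integrals$basis_centers[b]
    pops[a] <- pops[a] + d[b]
  }
  pops
}

.sqrtm <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  e$vectors %*% (t(e$vectors) * sqrt(e$values))
}

#' QM dipole moment of a density
#'
#' `mu = sum_A Z_A R_A - Tr[D r]` in atomic units.
#'
#' @param density `spin_density_pair` (AO)
#' @param integrals `integral_set`
#' @return length-3 dipole vector (a.u.)
#' @export
qm_dipole <- function(density, integrals) {
  geom <- integrals$provider_data$geom
  dt <- density$d_alpha + density$d_beta
  el <- vapply(integrals$dipole_ops, function(M) sum(M * dt), 0)
  colSums(geom$coords * geom$charges) - el
}
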