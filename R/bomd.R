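#' @title Born-Oppenheimer molecular dynamics
#' @name bomd
#' @description
#' Velocity-Verlet dynamics on a fully converged electronic surface at
#' every step -- the ground state or a tracked Delta-SCF excited state --
#' with the Bussi stochastic velocity-rescaling thermostat, frozen-atom
#' masks, analytic PPP forces (Hellmann-Feynman plus core and embedding
#' terms, with the induced dipoles at their variational optimum) or
#' finite-difference forces, and bit-reproducible checkpoint/restart.
NULL

#' MD configuration
#'
#' @param dt time step (fs, default 0.5)
#' @param n_steps number of steps
#' @param thermostat `"none"` (NVE) or `"bussi"`
#' @param temperature target temperature (K)
#' @param tau thermostat time constant (ps, default 0.1)
#' @param seed RNG seed for initial velocities and the thermostat
#' @param frozen_atom_indices atoms kept fixed (zero velocity and force)
#' @param force_mode `"analytic"` (PPP backend) or `"finite_difference"`
#' @param fd_step central-difference displacement (bohr)
#' @return named list of class `md_config`
#' @export
md_config <- function(dt = 0.5, n_steps = 100, thermostat = c("none", "bussi"),
                      temperature = 300, tau = 0.1, seed = 1,
                      frozen_atom_indices = integer(0),
                      force_mode = c("analytic", "finite_difference"),
                      fd_step = 1e-4) {
  thermostat <- match.arg(thermostat)
  force_mode <- match.arg(force_mode)
  if (dt <= 0) stop("md_config: dt must be > 0")
  if (thermostat == "bussi" && tau <= 0) stop("md_config: tau must be > 0")
  structure(list(dt = dt, n_steps = as.integer(n_steps),
                 thermostat = thermostat, temperature = temperature,
                 tau = tau, seed = as.integer(seed),
                 frozen_atom_indices = as.integer(frozen_atom_indices),
                 force_mode = force_mode, fd_step = fd_step),
            class = "md_config")
}

#' Define the electronic surface for MD
#'
#' @param params `ppp_params` for the QM model
#' @param sites optional `embedding_sites` environment
#' @param surface `"ground"` or `"deltascf"`
#' @param excitation `excitation_spec` (required for the Delta-SCF surface)
#' @param method Delta-SCF flavor, `"imom"` or `"step"`
#' @param ground_mode SCF mode for the ground surface
#' @param control [scf_control()] list
#' @param guess_mode guess strategy along the trajectory: `"grassmann"`
#'   (default), `"previous"` (previous converged density) or `"core"`
#' @param history_depth Grassmann history depth (default 6)
#' @param thole_a,cg_tol Thole damping factor and CG tolerance for the
#'   polarization solver
#' @return list of class `md_system`
#' @export
md_system_ppp <- function(params, sites = NULL,
                          surface = c("ground", "deltascf"),
                          excitation = NULL, method = c("imom", "step"),
                          ground_mode = c("restricted", "unrestricted"),
                          control = scf_control(tol_commutator = 1e-6,
                                                tol_energy = 1e-9,
                                                max_cycles = 300),
                          guess_mode = c("grassmann", "previous", "core"),
                          history_depth = 6, thole_a = 0.39, cg_tol = 1e-10) {
  surface <- match.arg(surface)
  method <- match.arg(method)
  ground_mode <- match.arg(ground_mode)
  guess_mode <- match.arg(guess_mode)
  if (surface == "deltascf" && is.null(excitation)) {
    stop("md_system_ppp: the deltascf surface needs an excitation spec")
  }
  ctx <- if (!is.null(sites)) {
    embedding_context(sites, thole_a = thole_a, cg_tol = cg_tol)
  } else {
    NULL
  }
  structure(list(kind = "ppp", params = params, ctx = ctx, surface = surface,
                 excitation = excitation, method = method,
                 ground_mode = ground_mode, control = control,
                 guess_mode = guess_mode, history_depth = history_depth),
            class = "md_system")
}

#' Analytic single-atom harmonic test surface
#'
#' `E = 1/2 k |r - center|^2`; used to validate the integrator and
#' thermostat against closed forms.
#'
#' @param k force constant (hartree / bohr^2)
#' @param center equilibrium position (bohr)
#' @return list of class `md_system`
#' @export
md_system_harmonic <- function(k, center = c(0, 0, 0)) {
  structure(list(kind = "harmonic", k = k, center = center,
                 surface = "ground", guess_mode = "none"),
            class = "md_system")
}

# ---- electronic solvers ---------------------------------------------------

elec_init <- function(system, geom) {
  if (system$kind == "harmonic") {
    dr <- sweep(geom$coords, 2, system$center)
    return(list(energy = 0.5 * system$k * sum(dr^2), e_qm = 0,
                e_fixed_elec = 0, e_pol = 0, dipole = c(0, 0, 0)))
  }
  ints <- ppp_integrals(geom, system$params)
  ne <- system$params$electrons
  na <- ceiling(ne / 2); nb <- ne - na
  ground <- scf_solve(ints, na, nb, guess = "core",
                      mode = system$ground_mode, embedding = system$ctx,
                      control = system$control)
  if (!ground$converged) stop("elec_init: ground SCF did not converge")
  if (system$surface == "ground") {
    ground$integrals <- ints
    return(ground)
  }
  ex <- deltascf_solve(ints, spec = system$excitation, ground = ground,
                       method = system$method, embedding = system$ctx,
                       control = system$control)
  if (!ex$converged) stop("elec_init: Delta-SCF did not converge")
  if (ex$collapsed) stop("elec_init: Delta-SCF collapsed onto the ground state")
  ex$integrals <- ints
  ex
}

elec_step <- function(system, geom, prev, history = NULL) {
  if (system$kind == "harmonic") return(elec_init(system, geom))
  ints <- ppp_integrals(geom, system$params)
  ne <- system$params$electrons
  na <- ceiling(ne / 2); nb <- ne - na
  # retry ladder for oscillating SCF cases: shallower DIIS, then damping
  controls <- list(system$control)
  c2 <- system$control; c2$diis_depth <- 2
  c2$max_cycles <- 2 * system$control$max_cycles
  c3 <- c2; c3$diis_depth <- 0; c3$damping <- 0.35
  controls <- c(controls, list(c2, c3))
  res <- NULL
  for (k in seq_along(controls)) {
    ctrl <- controls[[k]]
    if (system$surface == "ground") {
      guess <- switch(system$guess_mode,
        core = "core",
        previous = prev$density,
        grassmann = if (!is.null(history) && history_length(history) >= 2) {
          extrapolate_guess(history, geom)
        } else {
          prev$density
        })
      res <- scf_solve(ints, na, nb, guess = guess, mode = system$ground_mode,
                       embedding = system$ctx, control = ctrl)
    } else {
      tr <- track_state(prev, history = if (system$guess_mode == "grassmann")
        history else NULL, integrals = ints)
      guess <- if (system$guess_mode == "core") prev$density else tr$guess
      res <- deltascf_solve(ints, ground = NULL, method = system$method,
                            embedding = system$ctx, reference = tr$reference,
                            guess = guess, control = ctrl)
    }
    if (res$converged) break
    log_line("warn", sprintf("SCF retry %d at MD geometry (|[F,D]|=%.1e)",
                             k, res$commutator_norm))
  }
  if (!res$converged) {
    stop("elec_step: SCF did not converge at step geometry; trajectory halt")
  }
  res$n_scf_attempt <- k
  res$integrals <- ints
  res
}

# ---- forces ---------------------------------------------------------------

#' Forces on the atoms for a converged electronic state
#'
#' Analytic mode (PPP): Hellmann-Feynman terms from the hopping and Ohno
#' gamma derivatives, core-core and Born-Mayer terms, and the embedding
#' force `q_a * E_env(r_a)` with the induced dipoles at their variational
#' optimum (no response terms needed).  Finite-difference mode: central
#' differences of the full self-consistent energy with state tracking at
#' the displaced geometries.  Frozen atoms get exactly zero force.
#'
#' @param system `md_system`
#' @param geom current `geometry`
#' @param state converged electronic state at `geom`
#' @param config `md_config` (frozen mask, force mode, fd step)
#' @return n x 3 force matrix (hartree / bohr)
#' @export
compute_forces <- function(system, geom, state, config = md_config()) {
  n <- nrow(geom$coords)
  F <- if (system$kind == "harmonic") {
    -system$k * sweep(geom$coords, 2, system$center)
  } else if (config$force_mode == "analytic") {
    .ppp_forces_analytic(system, geom, state)
  } else {
    .forces_fd(system, geom, state, config$fd_step)
  }
  if (length(config$frozen_atom_indices) > 0) {
    F[config$frozen_atom_indices, ] <- 0
  }
  F
}

.ppp_forces_analytic <- function(system, geom, state) {
  params <- system$params
  ints <- state$integrals
  pos <- geom$coords
  na_at <- nrow(pos)
  ns <- length(params$site_energies)
  ba <- params$basis_atoms
  cores <- .ppp_cores(geom, params)
  zc <- cores$zc; ch <- cores$ch
  u <- params$hubbard_u
  da <- state$density$d_alpha; db <- state$density$d_beta
  dt <- da + db
  nocc <- diag(dt)
  F <- matrix(0, na_at, 3)
  addpair <- function(F, a, b, dEdr) {
    dr <- pos[a, ] - pos[b, ]
    r <- sqrt(sum(dr^2))
    g <- dEdr * dr / r
    F[a, ] <- F[a, ] - g
    F[b, ] <- F[b, ] + g
    F
  }
  # hopping + electron-electron gamma between basis sites
  for (i in seq_len(ns)) {
    for (j in seq_len(ns)) {
      if (j >= i) next
      a <- ba[i]; b <- ba[j]
      r <- sqrt(sum((pos[a, ] - pos[b, ])^2))
      dEdr <- 2 * dt[i, j] * ppp_dhopping(r, params)
      w2 <- nocc[i] * nocc[j] - da[i, j]^2 - db[i, j]^2
      gd <- if (params$ohno) ohno_dgamma(r, (u[i] + u[j]) / 2) else -1 / r^2
      dEdr <- dEdr + w2 * gd
      F <- addpair(F, a, b, dEdr)
    }
  }
  # electron-core attraction (site i electrons vs core at atom c)
  for (i in seq_len(ns)) {
    for (a in seq_len(na_at)) {
      if (a == ba[i] || zc[a] == 0) next
      r <- sqrt(sum((pos[ba[i], ] - pos[a, ])^2))
      gd <- if (params$ohno) ohno_dgamma(r, (u[i] + ch[a]) / 2) else -1 / r^2
      F <- addpair(F, ba[i], a, -nocc[i] * zc[a] * gd)
    }
  }
  # core-core + Born-Mayer
  rep_a <- rep(params$repulsion_a, length.out = na_at)
  for (a in 2:na_at) for (b in seq_len(a - 1)) {
    r <- sqrt(sum((pos[a, ] - pos[b, ])^2))
    dEdr <- 0
    if (zc[a] != 0 && zc[b] != 0) {
      gd <- if (params$ohno) ohno_dgamma(r, (ch[a] + ch[b]) / 2) else -1 / r^2
      dEdr <- dEdr + zc[a] * zc[b] * gd
    }
    ap <- sqrt(rep_a[a] * rep_a[b])
    if (ap > 0) {
      dEdr <- dEdr - ap / params$repulsion_rho * exp(-r / params$repulsion_rho)
    }
    if (dEdr != 0) F <- addpair(F, a, b, dEdr)
  }
  # embedding: net Lowdin charges in the total environment field
  if (!is.null(system$ctx)) {
    q <- qm_source_charges(state$density, ints)
    E <- env_total_field(system$ctx, pos, state$mu_induced)
    F <- F + q * E
  }
  F
}

.forces_fd <- function(system, geom, state, h) {
  n <- nrow(geom$coords)
  F <- matrix(0, n, 3)
  for (a in seq_len(n)) for (c_ in 1:3) {
    ep <- numeric(2)
    for (s in 1:2) {
      gp <- geom
      gp$coords[a, c_] <- gp$coords[a, c_] + c(h, -h)[s]
      st <- tryCatch(.fd_resolve(system, gp, state), error = function(e) {
        stop("finite-difference force: electronic solve failed at atom ", a,
             " component ", c_, " displacement ", c(h, -h)[s], ": ",
             conditionMessage(e))
      })
      ep[s] <- st$energy
    }
    F[a, c_] <- -(ep[1] - ep[2]) / (2 * h)
  }
  F
}

# re-solve at a displaced geometry with tracking from the current state
.fd_resolve <- function(system, geom, state) {
  ints <- ppp_integrals(geom, system$params)
  ne <- system$params$electrons
  na <- ceiling(ne / 2); nb <- ne - na
  if (system$surface == "ground") {
    res <- scf_solve(ints, na, nb, guess = state$density,
                     mode = system$ground_mode, embedding = system$ctx,
                     control = system$control)
  } else {
    res <- deltascf_solve(ints, ground = NULL, method = system$method,
                          embedding = system$ctx,
                          reference = state$reference,
                          guess = state$density, control = system$control)
    # displaced solution must stay in the tracked state
    S <- ints$overlap
    P <- t(state$reference$c_occ_alpha) %*% S %*%
      res$orbitals$c_alpha[, res$orbitals$occ_alpha, drop = FALSE]
    if (min(sqrt(colSums(P^2))) < 0.9) {
      stop("Delta-SCF state changed character (collapse) at displaced geometry")
    }
  }
  if (!res$converged) stop("SCF not converged")
  res
}

# ---- thermostat -----------------------------------------------------------

#' Bussi stochastic velocity-rescaling factor
#'
#' Canonical sampling through velocity rescaling: with `c = exp(-dt/tau)`
#' and target mean kinetic energy `Kbar = ndof kT / 2`,
#' `alpha^2 = c + (1-c) (Kbar/(ndof K)) (R1^2 + sum_(i=2)^(ndof) R_i^2)
#'  + 2 R1 sqrt(c (1-c) Kbar/(ndof K))`,
#' where `R1` is standard normal and the remaining sum is drawn as a
#' chi-squared (gamma) deviate.  Deterministic given the RNG state; the
#' `tau -> Inf` limit returns exactly 1.
#'
#' @param kinetic current kinetic energy (hartree, > 0)
#' @param ndof number of degrees of freedom
#' @param temperature target temperature (K)
#' @param tau time constant (ps)
#' @param dt time step (fs)
#' @return the velocity scaling factor `alpha`
#' @export
bussi_rescale <- function(kinetic, ndof, temperature, tau, dt) {
  stopifnot(kinetic > 0, ndof >= 1)
  c_ <- if (is.finite(tau)) exp(-dt / (tau * 1000)) else 1
  if (c_ == 1) return(1)
  kbar <- 0.5 * ndof * units_au$kboltz_hartree * temperature
  r1 <- rnorm(1)
  s <- if (ndof > 1) rgamma(1, shape = (ndof - 1) / 2, scale = 2) else 0
  ratio <- kbar / (ndof * kinetic)
  a2 <- c_ + (1 - c_) * ratio * (r1^2 + s) +
    2 * r1 * sqrt(c_ * (1 - c_) * ratio)
  sqrt(max(a2, 0))
}

# ---- driver ---------------------------------------------------------------

.kinetic_energy <- function(vel, masses_au, free) {
  0.5 * sum(masses_au[free] * rowSums(vel[free, , drop = FALSE]^2))
}

.state_energy_parts <- function(state) {
  list(e_pot = state$energy, e_qm = state$e_qm,
       e_fixed = state$e_fixed_elec, e_pol = state$e_pol)
}

.state_dipole <- function(state) {
  if (!is.null(state$density)) qm_dipole(state$density, state$integrals)
  else c(0, 0, 0)
}

#' Run Born-Oppenheimer molecular dynamics
#'
#' Velocity Verlet with a fully converged electronic solution at every
#' step.  Initial velocities (when not supplied) are Maxwell-Boltzmann at
#' the target temperature, frozen atoms zeroed and total momentum removed.
#' Checkpoints capture every piece of mutable state -- geometry,
#' velocities, forces, electronic state, extrapolation history and the RNG
#' stream -- so a restarted run is bit-identical to an uninterrupted one.
#'
#' @param system `md_system`
#' @param geom initial `geometry` (ignored on restart)
#' @param config `md_config`
#' @param velocities optional n x 3 initial velocities (bohr / atomic time
#'   unit)
#' @param initial_state optional pre-converged electronic state at `geom`
#'   (e.g. a freshly excited determinant for a sudden-switch protocol)
#' @param traj_path optional extended-XYZ file to append frames to
#' @param checkpoint_path optional RDS path written every
#'   `checkpoint_every` steps
#' @param checkpoint_every checkpoint interval (0 = never)
#' @param state_label label recorded in every frame
#' @param restart path to a checkpoint file to resume from
#' @return list with `frames` (list of `traj_frame`), `geometry`,
#'   `velocities`, `state` (final electronic state), `history`, `config`
#' @export
run_md <- function(system, geom, config, velocities = NULL,
                   initial_state = NULL, traj_path = NULL,
                   checkpoint_path = NULL, checkpoint_every = 0,
                   state_label = "GS", restart = NULL) {
  if (!is.null(restart)) {
    ck <- readRDS(restart)
    geom <- ck$geom; vel <- ck$velocities; state <- ck$state
    history <- ck$history; forces <- ck$forces
    start_step <- ck$step
    assign(".Random.seed", ck$rng, envir = globalenv())
    state_label <- ck$state_label
  } else {
    set.seed(config$seed)
    n <- nrow(geom$coords)
    free <- setdiff(seq_len(n), config$frozen_atom_indices)
    masses_au <- geom$masses * units_au$me_per_amu
    if (is.null(velocities)) {
      kt <- units_au$kboltz_hartree * config$temperature
      vel <- matrix(rnorm(3 * n), n, 3) * sqrt(kt / masses_au)
      vel[config$frozen_atom_indices, ] <- 0
      if (length(config$frozen_atom_indices) == 0 &&
          system$kind != "harmonic" && n > 1) {
        p <- colSums(vel * masses_au)
        vel <- sweep(vel, 2, p / sum(masses_au))
      }
    } else {
      vel <- velocities
      vel[config$frozen_atom_indices, ] <- 0
    }
    state <- if (is.null(initial_state)) elec_init(system, geom) else initial_state
    history <- NULL
    if (system$kind != "harmonic" && system$guess_mode == "grassmann") {
      history <- extrapolation_history(capacity = system$history_depth,
                                       overlap = diag(length(system$params$site_energies)))
      history_push(history, state$density, geom)
    }
    forces <- compute_forces(system, geom, state, config)
    start_step <- 0L
  }
  n <- nrow(geom$coords)
  free <- setdiff(seq_len(n), config$frozen_atom_indices)
  masses_au <- geom$masses * units_au$me_per_amu
  # total-momentum conservation only applies to isolated, fully mobile
  # molecular systems; an external (harmonic) potential keeps all 3N
  ndof <- 3 * length(free) -
    if (length(config$frozen_atom_indices) == 0 &&
        system$kind != "harmonic" && n > 1) 3 else 0
  dt_au <- config$dt * units_au$atu_per_fs

  frames <- list()
  scf_iters <- integer(0)
  record <- function(step, geomc, velc, statec) {
    parts <- .state_energy_parts(statec)
    kin <- .kinetic_energy(velc, masses_au, free)
    fr <- traj_frame(step_index = step, dt_fs = config$dt, geom = geomc,
                     velocities = velc, energy_total = parts$e_pot + kin,
                     energy_qm = parts$e_qm,
                     energy_fixed_elec = parts$e_fixed,
                     energy_pol = parts$e_pol,
                     dipole_moment = .state_dipole(statec),
                     kinetic_energy = kin, state_label = state_label)
    frames[[length(frames) + 1]] <<- fr
    if (!is.null(traj_path)) write_traj_frame(fr, traj_path)
    fr
  }
  if (start_step == 0L) record(0L, geom, vel, state)

  steps_todo <- if (start_step < config$n_steps) {
    seq.int(start_step + 1L, config$n_steps)
  } else {
    integer(0)
  }
  for (step in steps_todo) {
    acc <- forces / masses_au
    vel_half <- vel + 0.5 * dt_au * acc
    vel_half[config$frozen_atom_indices, ] <- 0
    coords_new <- geom$coords + dt_au * vel_half
    coords_new[config$frozen_atom_indices, ] <-
      geom$coords[config$frozen_atom_indices, , drop = FALSE]
    geom <- geometry(geom$symbols, coords_new, charges = geom$charges,
                     qm_charge = geom$qm_charge,
                     multiplicity_hint = geom$multiplicity_hint,
                     masses = geom$masses)
    state <- elec_step(system, geom, state, history)
    if (!is.null(state$n_iterations)) {
      scf_iters <- c(scf_iters, state$n_iterations)
    }
    if (!is.null(history)) history_push(history, state$density, geom)
    forces <- compute_forces(system, geom, state, config)
    vel <- vel_half + 0.5 * dt_au * forces / masses_au
    vel[config$frozen_atom_indices, ] <- 0
    if (config$thermostat == "bussi") {
      kin <- .kinetic_energy(vel, masses_au, free)
      a <- bussi_rescale(kin, ndof, config$temperature, config$tau, config$dt)
      vel[free, ] <- a * vel[free, , drop = FALSE]
    }
    kin <- .kinetic_energy(vel, masses_au, free)
    log_line("info", sprintf(
      "MD step %d  E_pot=%.10f  E_kin=%.8f  |F|max=%.3e",
      step, state$energy, kin, max(abs(forces))))
    record(step, geom, vel, state)
    if (checkpoint_every > 0 && !is.null(checkpoint_path) &&
        step %% checkpoint_every == 0) {
      saveRDS(list(step = step, geom = geom, velocities = vel, state = state,
                   history = history, forces = forces,
                   rng = get(".Random.seed", envir = globalenv()),
                   state_label = state_label),
              checkpoint_path)
    }
  }
  list(frames = frames, geometry = geom, velocities = vel, state = state,
       history = history, config = config, scf_iterations = scf_iters)
}
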