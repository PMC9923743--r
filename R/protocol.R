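#' Run the full photoinduced PCET cycle on a toy system
#'
#' The application protocol at desk scale: thermostatted ground-state
#' equilibration, a sudden switch to the charge-transfer surface by
#' electron promotion, tracked CT-surface dynamics during which the
#' forward proton transfer occurs, manual back electron transfer
#' ([back_electron_transfer()]) at the final CT frame, and tracked
#' dynamics of the recombined state during which the reverse proton
#' transfer occurs.  All three legs use the Bussi thermostat; the tight
#' coupling constant reflects the steep desk-scale transfer energetics.
#'
#' @param toy a system from [make_pcet_toy()]
#' @param n_equil,n_ct,n_back leg lengths (steps)
#' @param dt time step (fs)
#' @param temperature target temperature (K)
#' @param tau thermostat time constant (ps)
#' @param seeds integer seeds for the three legs
#' @param recombine_delay steps after the forward transfer event at which
#'   charge recombination is triggered
#' @param traj_dir optional directory for extended-XYZ trajectories
#' @return list with the three `run_md` results (`gs`, `ct`, `back`), the
#'   switch excitation energy, the CT-onset time, and the event tables
#'   `events_ct` / `events_back`
#' @export
run_pcet_cycle <- function(toy, n_equil = 100, n_ct = 1200, n_back = 1200,
                           dt = 0.5, temperature = 300, tau = 0.02,
                           seeds = c(21L, 22L, 23L), recombine_delay = 150L,
                           traj_dir = NULL) {
  tp <- function(name) {
    if (is.null(traj_dir)) NULL else file.path(traj_dir, name)
  }
  sys_gs <- md_system_ppp(toy$params, sites = toy$sites, surface = "ground",
                          ground_mode = "restricted")
  run_gs <- run_md(sys_gs, toy$geometry,
                   md_config(dt = dt, n_steps = n_equil,
                             thermostat = "bussi",
                             temperature = temperature, tau = tau,
                             seed = seeds[1]),
                   traj_path = tp("equil.xyz"), state_label = "GS")

  # sudden switch: promote at the equilibrated geometry
  ints1 <- ppp_integrals(run_gs$geometry, toy$params)
  sys_ct <- md_system_ppp(toy$params, sites = toy$sites,
                          surface = "deltascf",
                          excitation = toy$excitation, method = "imom")
  ct0 <- deltascf_solve(ints1, toy$excitation, run_gs$state,
                        method = "imom", embedding = sys_ct$ctx,
                        control = scf_control(tol_commutator = 1e-6,
                                              max_cycles = 400))
  if (!ct0$converged || ct0$collapsed) {
    stop("run_pcet_cycle: the sudden-switch CT state did not converge")
  }
  ct0$integrals <- ints1
  # vertical excitation from rest: the equilibration leg samples the
  # geometry, and the transfer dynamics then follow the CT surface's own
  # downhill path (the thermostat re-thermalizes the leg)
  run_ct <- run_md(sys_ct, run_gs$geometry,
                   md_config(dt = dt, n_steps = n_ct, thermostat = "bussi",
                             temperature = temperature, tau = tau,
                             seed = seeds[2]),
                   velocities = matrix(0, nrow(run_gs$geometry$coords), 3),
                   initial_state = ct0,
                   traj_path = tp("ct.xyz"), state_label = "CT")

  # charge recombination a fixed delay after the forward transfer: the
  # CT leg is deterministic for its seed, so truncating it at the
  # recombination frame reproduces that snapshot exactly (recombining
  # much later lets the proton sink into a covalent acceptor well from
  # which the recombined state cannot recall it before decaying)
  lab0 <- toy$pt_defs[[1]]$label
  pc_full <- pt_coordinates(run_ct$frames, toy$pt_defs)[[lab0]]
  ev_full <- detect_pt_events(pc_full, lab0)
  fwd_full <- ev_full[ev_full$direction == "forward", , drop = FALSE]
  snap <- run_ct
  if (nrow(fwd_full) > 0) {
    n_cut <- min(fwd_full$frame_index[1] - 1L + recombine_delay, n_ct)
    if (n_cut < n_ct) {
      snap <- run_md(sys_ct, run_gs$geometry,
                     md_config(dt = dt, n_steps = n_cut,
                               thermostat = "bussi",
                               temperature = temperature, tau = tau,
                               seed = seeds[2]),
                     velocities = matrix(0, nrow(run_gs$geometry$coords), 3),
                     initial_state = ct0, state_label = "CT")
    }
  }
  edge <- toy$atom_groups$donor[length(toy$atom_groups$donor)]
  bst <- back_electron_transfer(snap$state,
                                acceptor_atoms = toy$atom_groups$acceptor,
                                donor_atoms = edge,
                                embedding = sys_ct$ctx)
  if (!bst$converged) {
    stop("run_pcet_cycle: the back-electron-transfer state did not converge")
  }
  # recombination quench: the back-transfer leg starts from rest, so the
  # reverse proton transfer follows the recombined state's own downhill
  # path rather than the hot tail of the CT trajectory
  run_back <- run_md(sys_ct, snap$geometry,
                     md_config(dt = dt, n_steps = n_back,
                               thermostat = "bussi",
                               temperature = temperature, tau = tau,
                               seed = seeds[3]),
                     velocities = matrix(0, nrow(snap$geometry$coords), 3),
                     initial_state = bst,
                     traj_path = tp("back.xyz"), state_label = "GS")

  pc_ct <- pt_coordinates(run_ct$frames, toy$pt_defs)
  pc_back <- pt_coordinates(run_back$frames, toy$pt_defs)
  lab <- toy$pt_defs[[1]]$label
  onset <- ct_onset_time(dipole_state_series(run_ct$frames,
                                             toy$ct_threshold))
  list(gs = run_gs, ct = run_ct, back = run_back,
       excitation_energy = ct0$excitation_energy,
       ct_onset = onset,
       events_ct = detect_pt_events(pc_ct[[lab]], lab),
       events_back = detect_pt_events(pc_back[[lab]], lab))
}
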