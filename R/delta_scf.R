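#' @title Excited-state SCF (Delta-SCF): iMOM, STEP and diabatic tracking
#' @name delta_scf
#' @description
#' Excited states as single non-Aufbau determinants optimized with the same
#' SCF machinery as the ground state.  The guess is built by promoting one
#' electron from an occupied to a virtual orbital; collapse onto the ground
#' state during the iterations is avoided either by occupying, at each
#' cycle, the orbitals of maximum overlap with a fixed reference (iMOM) or
#' by level-shifting the complement of the reference space so Aufbau
#' filling tracks the target state (STEP).  Along a trajectory the
#' converged orbitals of the previous step act as the reference, which
#' keeps the state's character (e.g. charge-transfer) intact across
#' geometries: a natural quasidiabatic propagation.
NULL

#' Reference occupied orbitals for excited-state SCF
#'
#' @param c_occ_alpha,c_occ_beta matrices of S-orthonormal occupied MO
#'   coefficients (n x n_occ per spin)
#' @param overlap AO overlap (used to verify orthonormality)
#' @param provenance `"initial_guess"` or `"previous_md_step"`
#' @return object of class `reference_orbitals`
#' @export
reference_orbitals <- function(c_occ_alpha, c_occ_beta, overlap,
                               provenance = "initial_guess") {
  for (C in list(c_occ_alpha, c_occ_beta)) {
    g <- t(C) %*% overlap %*% C
    if (max(abs(g - diag(ncol(C)))) > 1e-8) {
      stop("reference_orbitals: columns not S-orthonormal")
    }
  }
  structure(list(c_occ_alpha = c_occ_alpha, c_occ_beta = c_occ_beta,
                 provenance = provenance), class = "reference_orbitals")
}

#' Specify a single-electron excitation
#'
#' @param spin `"alpha"` or `"beta"`
#' @param from occupied orbital: integer index, or the name of an atom
#'   group in `atom_groups` (resolved to the highest occupied orbital with
#'   > 50 percent Lowdin weight on that group)
#' @param to virtual orbital: integer index, or an atom-group name
#'   (resolved to the lowest virtual orbital with > 50 percent weight)
#' @param atom_groups named list of atom-index vectors used by labeled
#'   selectors
#' @return object of class `excitation_spec`
#' @export
excitation_spec <- function(spin = c("alpha", "beta"), from, to,
                            atom_groups = NULL) {
  spin <- match.arg(spin)
  structure(list(spin = spin, from = from, to = to,
                 atom_groups = atom_groups), class = "excitation_spec")
}

#' Lowdin weight of orbitals on an atom group
#'
#' @param C AO coefficient matrix (orbitals in columns)
#' @param integrals `integral_set`
#' @param atoms atom indices of the group
#' @return per-orbital weights in `[0, 1]`
#' @export
orbital_group_weights <- function(C, integrals, atoms) {
  Y <- .sqrtm(integrals$overlap) %*% C
  sel <- integrals$basis_centers %in% atoms
  colSums(Y[sel, , drop = FALSE]^2) / colSums(Y^2)
}

# resolve a from/to selector to an orbital index
.resolve_orbital <- function(sel, which, C, eps, occ, integrals, groups) {
  n <- ncol(C)
  if (is.numeric(sel)) {
    idx <- as.integer(sel)
    if (which == "occupied" && !(idx %in% occ)) {
      stop("excitation: from_orbital ", idx, " is not occupied")
    }
    if (which == "virtual" && (idx %in% occ)) {
      stop("excitation: to_orbital ", idx, " is not virtual")
    }
    return(idx)
  }
  atoms <- groups[[sel]]
  if (is.null(atoms)) stop("excitation: unknown atom group '", sel, "'")
  cand <- if (which == "occupied") occ else setdiff(seq_len(n), occ)
  w <- orbital_group_weights(C[, cand, drop = FALSE], integrals, atoms)
  qual <- which(w > 0.5)
  if (length(qual) == 0) {
    stop("excitation: selector '", sel, "' resolves to no ", which,
         " orbital (no Lowdin weight > 50%)")
  }
  # frontier pick: highest-energy qualifying occupied / lowest virtual;
  # ambiguous when a second qualifying, near-degenerate orbital has a
  # group weight within 5% of the chosen one
  pick <- if (which == "occupied") qual[which.max(eps[cand][qual])]
          else qual[which.min(eps[cand][qual])]
  others <- setdiff(qual, pick)
  if (length(others) > 0) {
    close_w <- abs(w[others] - w[pick]) < 0.05
    close_e <- abs(eps[cand][others] - eps[cand][pick]) < 0.02
    if (any(close_w & close_e)) {
      stop("excitation: selector '", sel, "' ambiguous (two qualifying ",
           "orbitals with weights within 5%)")
    }
  }
  cand[pick]
}

#' Build a promoted (non-Aufbau) guess density
#'
#' Moves one electron of the given spin from an occupied to a virtual
#' orbital of a converged ground-state result, returning the excited guess
#' density and the new occupied set as the reference orbitals.
#'
#' @param ground a converged `scf_result`
#' @param spec an `excitation_spec`
#' @param integrals `integral_set`
#' @return list with `density` (`spin_density_pair`, AO), `reference`
#'   (`reference_orbitals`), `occ_alpha`, `occ_beta`
#' @export
promote_electron <- function(ground, spec, integrals) {
  ob <- ground$orbitals
  C <- if (spec$spin == "alpha") ob$c_alpha else ob$c_beta
  eps <- if (spec$spin == "alpha") ob$eps_alpha else ob$eps_beta
  occ <- if (spec$spin == "alpha") ob$occ_alpha else ob$occ_beta
  from <- .resolve_orbital(spec$from, "occupied", C, eps, occ, integrals,
                           spec$atom_groups)
  to <- .resolve_orbital(spec$to, "virtual", C, eps, occ, integrals,
                         spec$atom_groups)
  if (from == to) stop("promote_electron: from and to orbitals coincide")
  occ_new <- sort(c(setdiff(occ, from), to))
  if (spec$spin == "alpha") {
    occa <- occ_new; occb <- ob$occ_beta
  } else {
    occa <- ob$occ_alpha; occb <- occ_new
  }
  da <- .density_from_occ(ob$c_alpha, occa)
  db <- .density_from_occ(ob$c_beta, occb)
  ref <- reference_orbitals(ob$c_alpha[, occa, drop = FALSE],
                            ob$c_beta[, occb, drop = FALSE],
                            integrals$overlap, provenance = "initial_guess")
  list(density = spin_density_pair(da, db), reference = ref,
       occ_alpha = occa, occ_beta = occb,
       from = from, to = to)
}

#' iMOM occupation selection
#'
#' Selects, among the freshly diagonalized orbitals, the `n_occ` with the
#' largest projection `p_j = || t(C_ref) S c_j ||_2` onto the (fixed)
#' reference occupied space.  Ties within 1e-8 resolve to the lower
#' orbital energy and are logged.
#'
#' @param c_new full AO coefficient matrix at the current cycle
#' @param c_ref reference occupied coefficients (n x n_occ)
#' @param overlap AO overlap
#' @return occupied column indices (length `ncol(c_ref)`)
#' @export
imom_select_occupations <- function(c_new, c_ref, overlap) {
  n_occ <- ncol(c_ref)
  P <- t(c_ref) %*% overlap %*% c_new           # n_occ x n
  p <- sqrt(colSums(P^2))
  ord <- order(p, decreasing = TRUE)            # stable: ties keep low index
  sel <- ord[seq_len(n_occ)]
  if (length(p) > n_occ) {
    boundary <- p[ord[n_occ]] - p[ord[n_occ + 1]]
    if (abs(boundary) < 1e-8) {
      log_line("info", "iMOM projection tie at the selection boundary; ",
               "picking the lower-energy orbital")
    }
  }
  sel
}

#' STEP level shift of a Fock matrix
#'
#' Raises the complement of the reference occupied space:
#' `F' = F + shift * (S - S C_ref t(C_ref) S)`, so that Aufbau filling of
#' `F'` occupies the reference-tracked state.
#'
#' @param fock per-spin Fock matrix (AO)
#' @param c_ref reference occupied coefficients for that spin
#' @param overlap AO overlap
#' @param shift level shift (hartree, > 0; 0 returns `fock` unchanged)
#' @return shifted Fock matrix
#' @export
step_shift_fock <- function(fock, c_ref, overlap, shift) {
  if (shift == 0) return(fock)
  if (shift < 0) stop("step_shift_fock: shift must be >= 0")
  SC <- overlap %*% c_ref
  fock + shift * (overlap - SC %*% t(SC))
}

# automatic STEP shift: reference expectation energies vs lowest eigenvalue
.step_auto_shift <- function(fock, c_ref, X, margin) {
  eps_ref <- diag(t(c_ref) %*% fock %*% c_ref)
  fon <- t(X) %*% fock %*% X
  emin <- min(eigen((fon + t(fon)) / 2, symmetric = TRUE,
                    only.values = TRUE)$values)
  max(max(eps_ref) - emin, 0) + margin
}

#' Solve for an excited-state determinant
#'
#' Runs an open-shell SCF that converges on the excited determinant
#' selected by `spec`, using either iMOM occupation selection or the STEP
#' level shift with an automatically chosen shift (reference-span top
#' energy minus lowest eigenvalue, plus `step_margin`).  After
#' convergence, the occupied space is projected onto the ground occupied
#' space: if every projection exceeds `collapse_tol` the result is flagged
#' `collapsed`.
#'
#' @param integrals `integral_set`
#' @param spec `excitation_spec` (ignored when `reference` is supplied
#'   together with `guess`)
#' @param ground converged ground-state `scf_result` (also the energy zero
#'   for the excitation energy)
#' @param method `"imom"` or `"step"`
#' @param embedding optional embedding context; the excited state then
#'   carries its own self-consistent environment response
#' @param reference optional `reference_orbitals` override (used along MD:
#'   the previous step's converged orbitals)
#' @param guess optional `spin_density_pair` guess override (used along
#'   MD: the extrapolated density)
#' @param control [scf_control()] list
#' @param step_margin STEP shift margin (hartree, default 1)
#' @param collapse_tol per-orbital ground-space projection above which the
#'   state counts as collapsed (default 0.999)
#' @return `scf_result` with extra fields `excitation_energy`,
#'   `collapsed`, `reference` (the converged occupied orbitals, for
#'   tracking), `method`
#' @export
deltascf_solve <- function(integrals, spec, ground,
                           method = c("imom", "step"), embedding = NULL,
                           reference = NULL, guess = NULL,
                           control = scf_control(), step_margin = 1.0,
                           collapse_tol = 0.999) {
  method <- match.arg(method)
  S <- integrals$overlap
  X <- lowdin_transform(S)
  if (is.null(reference) || is.null(guess)) {
    prom <- promote_electron(ground, spec, integrals)
    if (is.null(reference)) reference <- prom$reference
    if (is.null(guess)) guess <- prom$density
  }
  na <- ncol(reference$c_occ_alpha)
  nb <- ncol(reference$c_occ_beta)

  occ_select <- NULL; fock_shift <- NULL
  if (method == "imom") {
    occ_select <- function(C, eps, spin) {
      cr <- if (spin == "alpha") reference$c_occ_alpha else reference$c_occ_beta
      imom_select_occupations(C, cr, S)
    }
  } else {
    # STEP: raise the complement of the reference occupied space so that
    # Aufbau filling of the shifted Fock tracks the reference state; the
    # shift magnitude is recomputed from the reference every cycle
    fock_shift <- function(F, spin, c_occ) {
      cr <- if (spin == "alpha") reference$c_occ_alpha else reference$c_occ_beta
      shift <- .step_auto_shift(F, cr, X, step_margin)
      step_shift_fock(F, cr, S, shift)
    }
  }
  res <- scf_solve(integrals, na, nb, guess = guess, mode = "unrestricted",
                   embedding = embedding, control = control,
                   occ_select = occ_select, fock_shift = fock_shift)

  # collapse detection: per-orbital projection onto the ground occupied space
  collapsed <- FALSE
  if (res$converged && !is.null(ground)) {
    proj_spin <- function(C, occ, Cg, occg) {
      if (length(occ) == 0) return(numeric(0))
      Cgo <- Cg[, occg, drop = FALSE]
      P <- t(Cgo) %*% S %*% C[, occ, drop = FALSE]
      sqrt(colSums(P^2))
    }
    pa <- proj_spin(res$orbitals$c_alpha, res$orbitals$occ_alpha,
                    ground$orbitals$c_alpha, ground$orbitals$occ_alpha)
    pb <- proj_spin(res$orbitals$c_beta, res$orbitals$occ_beta,
                    ground$orbitals$c_beta, ground$orbitals$occ_beta)
    collapsed <- all(c(pa, pb) > collapse_tol)
    if (collapsed) log_line("warn", "Delta-SCF solution collapsed onto the ",
                            "ground-state determinant")
  }
  res$excitation_energy <- if (is.null(ground)) NA_real_ else
    res$energy - ground$energy
  res$collapsed <- collapsed
  res$method <- method
  res$reference <- reference_orbitals(
    res$orbitals$c_alpha[, res$orbitals$occ_alpha, drop = FALSE],
    res$orbitals$c_beta[, res$orbitals$occ_beta, drop = FALSE],
    S, provenance = "previous_md_step")
  res
}

#' Prepare the back-electron-transfer state
#'
#' Charge recombination after a photoinduced electron (and proton)
#' transfer: the transferred alpha electron of a converged CT state is
#' manually demoted from its acceptor-localized orbital back into the
#' donor-side orbital, and the resulting closed-shell-type determinant is
#' converged with iMOM tracking.  Immediately after recombination this
#' state is typically higher in energy than the diradical it came from
#' (charge separation persists until the reverse proton transfer), so it
#' must be tracked rather than found by Aufbau filling.
#'
#' @param ct_state a converged CT `scf_result` (with its `integrals`)
#' @param acceptor_atoms,donor_atoms atom-index groups locating the
#'   transferred electron and its destination
#' @param embedding optional embedding context
#' @param control [scf_control()] list
#' @return a tracked `scf_result` for the recombined state
#' @export
back_electron_transfer <- function(ct_state, acceptor_atoms, donor_atoms,
                                   embedding = NULL,
                                   control = scf_control(
                                     tol_commutator = 1e-6,
                                     max_cycles = 400)) {
  ints <- ct_state$integrals
  if (is.null(ints)) stop("back_electron_transfer: ct_state lacks integrals")
  S <- ints$overlap
  Ca <- ct_state$orbitals$c_alpha
  occa <- ct_state$orbitals$occ_alpha
  vira <- setdiff(seq_len(ints$n_basis), occa)
  w_occ <- orbital_group_weights(Ca[, occa, drop = FALSE], ints,
                                 acceptor_atoms)
  w_vir <- orbital_group_weights(Ca[, vira, drop = FALSE], ints,
                                 donor_atoms)
  from <- occa[which.max(w_occ)]
  to <- vira[which.max(w_vir)]
  occ_new <- sort(c(setdiff(occa, from), to))
  Da <- .density_from_occ(Ca, occ_new)
  Cb <- ct_state$orbitals$c_beta
  occb <- ct_state$orbitals$occ_beta
  Db <- .density_from_occ(Cb, occb)
  ref <- reference_orbitals(Ca[, occ_new, drop = FALSE],
                            Cb[, occb, drop = FALSE], S,
                            provenance = "initial_guess")
  res <- deltascf_solve(ints, ground = NULL, method = "imom",
                        embedding = embedding, reference = ref,
                        guess = spin_density_pair(Da, Db),
                        control = control)
  res$integrals <- ints
  res
}

#' Reference and guess for the next MD step of a tracked excited state
#'
#' The converged occupied orbitals of the previous step become the
#' reference (for iMOM selection or the STEP shift); the guess density is
#' the Grassmann extrapolation when at least two history entries exist,
#' else the previous converged density.  A collapsed previous step halts
#' the trajectory.
#'
#' @param previous the previous step's `deltascf_solve` result
#' @param history optional `extrapolation_history`
#' @param integrals `integral_set` at the NEW geometry (for the descriptor)
#' @return list `(reference, guess)`
#' @export
track_state <- function(previous, history = NULL, integrals = NULL) {
  if (!previous$converged) stop("track_state: previous step not converged")
  if (isTRUE(previous$collapsed)) {
    stop("track_state: previous step collapsed onto the ground state; halt")
  }
  guess <- previous$density
  if (!is.null(history) && history_length(history) >= 2 &&
      !is.null(integrals)) {
    guess <- extrapolate_guess(history, integrals$provider_data$geom)
  }
  list(reference = previous$reference, guess = guess)
}
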