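#' @title Pariser-Parr-Pople pi-electron model provider
#' @name ppp
#' @description
#' A semiempirical pi-electron Hamiltonian with one basis function per pi
#' site: on-site energies, distance-dependent hopping
#' `t(r) = t0 * exp(-(r - r0)/lambda)`, on-site Hubbard repulsion and
#' Ohno-interpolated two-center repulsion
#' `gamma(r) = U / sqrt(1 + (U r)^2)` (atomic units; `U` is the pair
#' average).  Atoms without a basis function act as bare cores (e.g. a
#' mobile proton) coupled through Ohno-damped electron-core and core-core
#' terms with a per-atom core hardness, plus an optional Born-Mayer
#' short-range core repulsion `A exp(-r/rho)` that keeps nuclear fusion off
#' the potential surface.  All geometry dependence is smooth, so the model
#' has analytic forces.
NULL

#' PPP model parameters
#'
#' @param site_energies on-site energies (hartree), one per basis site
#' @param hubbard_u on-site repulsion U_i (hartree), one per basis site;
#'   all must be positive
#' @param t0 hopping amplitude at reference distance `r0` (hartree,
#'   typically negative)
#' @param r0 reference bond length (bohr)
#' @param lambda hopping decay length (bohr)
#' @param electrons number of pi electrons
#' @param core_charges per-ATOM core charge (e); atoms beyond the basis
#'   sites are bare cores
#' @param basis_atoms atom index carrying each basis function (default:
#'   the first `length(site_energies)` atoms)
#' @param core_hardness per-atom Ohno hardness for electron-core and
#'   core-core damping (hartree); defaults to `0.8` everywhere
#' @param ohno use Ohno interpolation for two-center terms (else bare 1/r)
#' @param repulsion_a,repulsion_rho Born-Mayer core-core repulsion:
#'   per-atom amplitudes (hartree, geometric pair mixing
#'   `sqrt(A_i A_j)`, recycled over atoms) and a common range (bohr);
#'   `repulsion_a = 0` disables it
#' @return object of class `ppp_params`
#' @export
ppp_params <- function(site_energies, hubbard_u, t0 = -0.2, r0 = 2.7,
                       lambda = 2.0, electrons = length(site_energies),
                       core_charges = NULL, basis_atoms = NULL,
                       core_hardness = NULL, ohno = TRUE,
                       repulsion_a = 0, repulsion_rho = 1.0) {
  ns <- length(site_energies)
  if (length(hubbard_u) == 1) hubbard_u <- rep(hubbard_u, ns)
  if (any(hubbard_u <= 0)) stop("ppp_params: all U_i must be > 0")
  if (electrons > 2 * ns) stop("ppp_params: electrons > 2 * n_sites")
  if (is.null(basis_atoms)) basis_atoms <- seq_len(ns)
  structure(list(site_energies = as.numeric(site_energies),
                 hubbard_u = as.numeric(hubbard_u), t0 = t0, r0 = r0,
                 lambda = lambda, electrons = as.integer(electrons),
                 core_charges = core_charges,
                 basis_atoms = as.integer(basis_atoms),
                 core_hardness = core_hardness, ohno = ohno,
                 repulsion_a = as.numeric(repulsion_a),
                 repulsion_rho = repulsion_rho),
            class = "ppp_params")
}

# Ohno-interpolated two-center repulsion and its radial derivative
ohno_gamma <- function(r, u_avg) u_avg / sqrt(1 + (u_avg * r)^2)
ohno_dgamma <- function(r, u_avg) -u_avg^3 * r * (1 + (u_avg * r)^2)^-1.5

ppp_hopping <- function(r, params) params$t0 * exp(-(r - params$r0) / params$lambda)
ppp_dhopping <- function(r, params) -ppp_hopping(r, params) / params$lambda

# resolve per-atom core charges / hardness against a geometry
.ppp_cores <- function(geom, params) {
  na <- length(geom$symbols)
  zc <- params$core_charges
  if (is.null(zc)) zc <- geom$charges
  if (length(zc) != na) stop("ppp_integrals: core_charges length mismatch")
  ch <- params$core_hardness
  if (is.null(ch)) ch <- rep(0.8, na)
  if (length(ch) == 1) ch <- rep(ch, na)
  list(zc = zc, ch = ch)
}

#' Compute PPP model integrals for a geometry
#'
#' One basis function per pi site; overlap is the identity.  The core
#' Hamiltonian diagonal carries the on-site energy plus Ohno-damped
#' attraction to every other atomic core; the off-diagonal carries the
#' distance-dependent hopping.  The two-electron tensor has only `(ii|jj)`
#' elements (`gamma_ij`, with `gamma_ii = U_i`).  The electronic dipole
#' operator is site-diagonal with the site positions as matrix elements.
#'
#' @param geom a `geometry`; atoms listed in `params$basis_atoms` carry the
#'   pi basis functions, remaining atoms are bare cores
#' @param params a `ppp_params`
#' @return an `integral_set`
#' @export
ppp_integrals <- function(geom, params) {
  ns <- length(params$site_energies)
  cores <- .ppp_cores(geom, params)
  zc <- cores$zc; ch <- cores$ch
  na <- length(geom$symbols)
  pos <- geom$coords
  ba <- params$basis_atoms
  if (na > 1 && min(dist(pos)) < 1e-3) {
    stop("ppp_integrals: sites closer than 1e-3 bohr")
  }
  u <- params$hubbard_u
  # electron-electron gamma between basis sites
  gam <- matrix(0, ns, ns)
  hcore <- matrix(0, ns, ns)
  for (i in seq_len(ns)) {
    gam[i, i] <- u[i]
    for (j in seq_len(ns)) {
      if (i == j) next
      r <- sqrt(sum((pos[ba[i], ] - pos[ba[j], ])^2))
      gam[i, j] <- if (params$ohno) ohno_gamma(r, (u[i] + u[j]) / 2) else 1 / r
      hcore[i, j] <- ppp_hopping(r, params)
    }
  }
  # diagonal: on-site energy + attraction to all other cores
  for (i in seq_len(ns)) {
    hii <- params$site_energies[i]
    for (a in seq_len(na)) {
      if (a == ba[i] || zc[a] == 0) next
      r <- sqrt(sum((pos[ba[i], ] - pos[a, ])^2))
      g <- if (params$ohno) ohno_gamma(r, (u[i] + ch[a]) / 2) else 1 / r
      hii <- hii - zc[a] * g
    }
    hcore[i, i] <- hii
  }
  eri <- array(0, c(ns, ns, ns, ns))
  for (i in seq_len(ns)) for (j in seq_len(ns)) eri[i, i, j, j] <- gam[i, j]
  enuc <- 0
  rep_a <- rep(params$repulsion_a, length.out = na)
  if (na > 1) {
    for (a in 2:na) for (b in seq_len(a - 1)) {
      r <- sqrt(sum((pos[a, ] - pos[b, ])^2))
      if (zc[a] != 0 && zc[b] != 0) {
        g <- if (params$ohno) ohno_gamma(r, (ch[a] + ch[b]) / 2) else 1 / r
        enuc <- enuc + zc[a] * zc[b] * g
      }
      ap <- sqrt(rep_a[a] * rep_a[b])
      if (ap > 0) enuc <- enuc + ap * exp(-r / params$repulsion_rho)
    }
  }
  dip <- lapply(1:3, function(c_) diag(pos[ba, c_], nrow = ns))
  integral_set(overlap = diag(ns), hcore = hcore, eri = eri,
               dipole_ops = dip, nuclear_repulsion = enuc,
               basis_centers = ba, provider = "ppp",
               provider_data = list(params = params, geom = geom,
                                    core_charges = zc, core_hardness = ch))
}
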