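#' @title Exact diagonalization in the determinant basis
#' @name fci
#' @description
#' Full configuration interaction over the (Lowdin-orthonormalized) orbital
#' basis of an integral set, used throughout the package as the variational
#' reference: the adiabatic eigenstates against which the diabatic
#' single-determinant Delta-SCF states are compared.
NULL

# transform the 4-index ERI tensor into an orthonormal basis: (pq|rs) =
# sum_ijkl X_ip X_jq X_kr X_ls (ij|kl)
.transform_eri <- function(eri, X) {
  n <- dim(eri)[1]
  g <- eri
  for (leg in 1:4) {
    g <- aperm(g, c(2, 3, 4, 1))              # rotate target leg to the end
    g <- array(matrix(g, n^3, n) %*% X, c(n, n, n, n))
  }
  g
}

# sorted occupation strings (columns) for k electrons in n orbitals
.strings <- function(n, k) {
  if (k == 0) return(matrix(integer(0), nrow = 0, ncol = 1))
  combn(n, k)
}

# phase and legality of the single replacement p -> q in sorted string s
.single_phase <- function(s, p, q) {
  lo <- min(p, q); hi <- max(p, q)
  nbet <- sum(s > lo & s < hi)
  (-1)^nbet
}

# classify a string pair: list(degree, holes, parts, phase) or NULL if > 2
.string_diff <- function(s1, s2) {
  holes <- setdiff(s1, s2)
  parts <- setdiff(s2, s1)
  d <- length(holes)
  if (d > 2) return(NULL)
  if (d == 0) return(list(degree = 0L, phase = 1))
  holes <- sort(holes); parts <- sort(parts)
  if (d == 1) {
    return(list(degree = 1L, holes = holes, parts = parts,
                phase = .single_phase(s1, holes[1], parts[1])))
  }
  ph1 <- .single_phase(s1, holes[1], parts[1])
  s_mid <- sort(c(setdiff(s1, holes[1]), parts[1]))
  ph2 <- .single_phase(s_mid, holes[2], parts[2])
  list(degree = 2L, holes = holes, parts = parts, phase = ph1 * ph2)
}

#' Exact diagonalization of an electronic Hamiltonian
#'
#' Builds the full Hamiltonian matrix over all Slater determinants with the
#' given spin-orbital occupations (in the Lowdin-orthonormalized basis of
#' `integrals`) and diagonalizes it.
#'
#' @param integrals an `integral_set`
#' @param n_alpha,n_beta numbers of alpha and beta electrons
#' @param n_roots number of low-lying states for which spin-summed
#'   one-particle density matrices (orthonormal basis) are also returned
#' @return list with `energies` (ascending, including nuclear repulsion),
#'   `vectors` (determinant-basis eigenvectors, one column per state),
#'   `rdm1` (list of orthonormal-basis 1-RDMs for the first `n_roots`
#'   states), `dipoles` (QM dipole vectors, a.u., for those states), `X`
#'   (the Lowdin orthonormalization used) and the determinant bookkeeping.
#' @export
exact_diagonalization <- function(integrals, n_alpha, n_beta, n_roots = 4) {
  n <- integrals$n_basis
  X <- lowdin_transform(integrals$overlap)
  h <- t(X) %*% integrals$hcore %*% X
  g <- .transform_eri(integrals$eri, X)
  sa <- .strings(n, n_alpha)
  sb <- .strings(n, n_beta)
  nA <- ncol(sa); nB <- ncol(sb)
  ndet <- nA * nB
  if (ndet > 1e6) stop("exact_diagonalization: determinant-space overflow")

  # precompute string-pair difference tables per spin
  diffA <- vector("list", nA * nA)
  for (i in seq_len(nA)) for (j in seq_len(nA)) {
    diffA[[(i - 1) * nA + j]] <- .string_diff(sa[, i], sa[, j])
  }
  diffB <- vector("list", nB * nB)
  for (i in seq_len(nB)) for (j in seq_len(nB)) {
    diffB[[(i - 1) * nB + j]] <- .string_diff(sb[, i], sb[, j])
  }

  gJ <- matrix(g, n * n, n * n)      # (ij|kl) with row (ij)
  idx <- function(p, q) p + n * (q - 1)

  # single-excitation effective element: h_pq + sum_r_occ_sigma [(pq|rr) -
  # (pr|rq)] + sum_r_occ_other (pq|rr)
  single_elem <- function(p, q, occ_same, occ_other) {
    v <- h[p, q]
    for (r in occ_same) {
      if (r == p) next
      v <- v + g[p, q, r, r] - g[p, r, r, q]
    }
    for (r in occ_other) v <- v + g[p, q, r, r]
    v
  }

  diag_elem <- function(oa, ob) {
    v <- 0
    for (p in oa) v <- v + h[p, p]
    for (p in ob) v <- v + h[p, p]
    for (p in oa) for (q in oa) v <- v + 0.5 * (g[p, p, q, q] - g[p, q, q, p])
    for (p in ob) for (q in ob) v <- v + 0.5 * (g[p, p, q, q] - g[p, q, q, p])
    for (p in oa) for (q in ob) v <- v + g[p, p, q, q]
    v
  }

  H <- matrix(0, ndet, ndet)
  det_id <- function(ia, ib) (ib - 1) * nA + ia
  for (ia in seq_len(nA)) for (ib in seq_len(nB)) {
    I <- det_id(ia, ib)
    oa <- sa[, ia]; ob <- sb[, ib]
    for (ja in seq_len(nA)) {
      dA <- diffA[[(ia - 1) * nA + ja]]
      if (is.null(dA)) next
      for (jb in seq_len(nB)) {
        J <- det_id(ja, jb)
        if (J < I) next
        dB <- diffB[[(ib - 1) * nB + jb]]
        if (is.null(dB)) next
        dtot <- dA$degree + dB$degree
        if (dtot > 2) next
        val <- 0
        if (dtot == 0) {
          val <- diag_elem(oa, ob)
        } else if (dtot == 1) {
          if (dA$degree == 1) {
            val <- dA$phase * single_elem(dA$holes, dA$parts, oa, ob)
          } else {
            val <- dB$phase * single_elem(dB$holes, dB$parts, ob, oa)
          }
        } else if (dA$degree == 2) {
          p <- dA$holes; q <- dA$parts
          val <- dA$phase * (g[p[1], q[1], p[2], q[2]] -
                               g[p[1], q[2], p[2], q[1]])
        } else if (dB$degree == 2) {
          p <- dB$holes; q <- dB$parts
          val <- dB$phase * (g[p[1], q[1], p[2], q[2]] -
                               g[p[1], q[2], p[2], q[1]])
        } else {
          val <- dA$phase * dB$phase *
            g[dA$holes, dA$parts, dB$holes, dB$parts]
        }
        H[I, J] <- H[J, I] <- val
      }
    }
  }
  eig <- eigen(H, symmetric = TRUE)
  ord <- order(eig$values)
  energies <- eig$values[ord] + integrals$nuclear_repulsion
  vectors <- eig$vectors[, ord, drop = FALSE]

  n_roots <- min(n_roots, ndet)
  rdm1 <- vector("list", n_roots)
  dipoles <- vector("list", n_roots)
  geom <- integrals$provider_data$geom
  dip_on <- lapply(integrals$dipole_ops, function(M) t(X) %*% M %*% X)
  for (s in seq_len(n_roots)) {
    D <- .fci_rdm1(vectors[, s], sa, sb, nA, nB, diffA, diffB, n)
    rdm1[[s]] <- D
    el <- vapply(dip_on, function(M) sum(M * D), 0)
    nuc <- if (!is.null(geom)) colSums(geom$coords * geom$charges) else c(0, 0, 0)
    dipoles[[s]] <- nuc - el
  }
  list(energies = energies, vectors = vectors, rdm1 = rdm1,
       dipoles = dipoles, X = X, strings_alpha = sa, strings_beta = sb)
}

# spin-summed one-particle density matrix of a CI vector
.fci_rdm1 <- function(cvec, sa, sb, nA, nB, diffA, diffB, n) {
  D <- matrix(0, n, n)
  det_id <- function(ia, ib) (ib - 1) * nA + ia
  for (ia in seq_len(nA)) for (ib in seq_len(nB)) {
    cI <- cvec[det_id(ia, ib)]
    if (abs(cI) < 1e-14) next
    # alpha part: same beta string
    for (ja in seq_len(nA)) {
      dA <- diffA[[(ia - 1) * nA + ja]]
      if (is.null(dA) || dA$degree > 1) next
      cJ <- cvec[det_id(ja, ib)]
      if (abs(cJ) < 1e-14) next
      if (dA$degree == 0) {
        for (p in sa[, ia]) D[p, p] <- D[p, p] + cI * cJ
      } else {
        D[dA$holes, dA$parts] <- D[dA$holes, dA$parts] + dA$phase * cI * cJ
      }
    }
    # beta part: same alpha string
    for (jb in seq_len(nB)) {
      dB <- diffB[[(ib - 1) * nB + jb]]
      if (is.null(dB) || dB$degree > 1) next
      cJ <- cvec[det_id(ia, jb)]
      if (abs(cJ) < 1e-14) next
      if (dB$degree == 0) {
        for (p in sb[, ib]) D[p, p] <- D[p, p] + cI * cJ
      } else {
        D[dB$holes, dB$parts] <- D[dB$holes, dB$parts] + dB$phase * cI * cJ
      }
    }
  }
  (D + t(D)) / 2
}
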