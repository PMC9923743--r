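#' @title Minimal s-type Gaussian integral provider
#' @name integrals_gaussian
#' @description
#' Closed-form one- and two-electron integrals over contracted s-type
#' Gaussians (Boys F0/F1 only).  Together with the PPP provider this
#' implements the common integral contract consumed by the SCF engine:
#' overlap, core Hamiltonian, two-electron tensor in chemists' notation,
#' electronic dipole matrices and the nuclear repulsion.
NULL

# Boys functions F0, F1 with series switch at small argument
boys_f0 <- function(t) {
  out <- numeric(length(t))
  small <- t < 1e-10
  out[small] <- 1 - t[small] / 3
  tb <- t[!small]
  out[!small] <- 0.5 * sqrt(pi / tb) * (2 * pnorm(sqrt(2 * tb)) - 1)
  out
}

boys_f1 <- function(t) {
  out <- numeric(length(t))
  small <- t < 1e-6
  out[small] <- 1 / 3 - t[small] / 5 + t[small]^2 / 14
  tb <- t[!small]
  out[!small] <- (boys_f0(tb) - exp(-tb)) / (2 * tb)
  out
}

#' STO-3G style s-type contractions for H and He
#'
#' @return basis specification: a named list, one entry per element, each a
#'   list of shells given as k x 2 matrices of (exponent, contraction
#'   coefficient) pairs for normalized primitives.
#' @export
basis_sto3g <- function() {
  co <- c(0.15432897, 0.53532814, 0.44463454)
  list(
    H  = list(cbind(c(3.42525091, 0.62391373, 0.16885540), co)),
    He = list(cbind(c(6.36242139, 1.15892300, 0.31364979), co))
  )
}

# expand a basis spec over a geometry into a flat list of contracted
# functions; contraction coefficients are renormalized so <i|i> = 1
.expand_basis <- function(geom, basis_spec) {
  funs <- list()
  for (a in seq_along(geom$symbols)) {
    sym <- geom$symbols[a]
    shells <- basis_spec[[sym]]
    if (is.null(shells)) stop("gaussian_integrals: no basis entry for ", sym)
    for (sh in shells) {
      expo <- sh[, 1]
      coef <- sh[, 2] * (2 * expo / pi)^0.75   # normalized primitives
      funs[[length(funs) + 1]] <- list(center = geom$coords[a, ],
                                       expo = expo, coef = coef, atom = a)
    }
  }
  # renormalize contractions
  for (i in seq_along(funs)) {
    s <- .contr_pair(funs[[i]], funs[[i]], .prim_overlap)
    funs[[i]]$coef <- funs[[i]]$coef / sqrt(s)
  }
  funs
}

# contract a primitive pair kernel over two contracted functions
.contr_pair <- function(fa, fb, kernel, ...) {
  acc <- 0
  for (i in seq_along(fa$expo)) {
    for (j in seq_along(fb$expo)) {
      acc <- acc + fa$coef[i] * fb$coef[j] *
        kernel(fa$expo[i], fa$center, fb$expo[j], fb$center, ...)
    }
  }
  acc
}

.prim_overlap <- function(a, A, b, B) {
  p <- a + b
  r2 <- sum((A - B)^2)
  (pi / p)^1.5 * exp(-a * b / p * r2)
}

.prim_kinetic <- function(a, A, b, B) {
  p <- a + b
  q <- a * b / p
  r2 <- sum((A - B)^2)
  q * (3 - 2 * q * r2) * .prim_overlap(a, A, b, B)
}

.prim_attraction <- function(a, A, b, B, C) {
  p <- a + b
  r2 <- sum((A - B)^2)
  P <- (a * A + b * B) / p
  t <- p * sum((P - C)^2)
  (2 * pi / p) * exp(-a * b / p * r2) * boys_f0(t)
}

# gradient of the attraction kernel w.r.t. the attraction center C
.prim_attraction_grad <- function(a, A, b, B, C) {
  p <- a + b
  r2 <- sum((A - B)^2)
  P <- (a * A + b * B) / p
  t <- p * sum((P - C)^2)
  (2 * pi / p) * exp(-a * b / p * r2) * boys_f1(t) * 2 * p * (P - C)
}

.prim_dipole <- function(a, A, b, B, comp) {
  p <- a + b
  P <- (a * A + b * B) / p
  P[comp] * .prim_overlap(a, A, b, B)
}

.prim_eri <- function(a, A, b, B, c_, C, d, D) {
  p <- a + b
  q <- c_ + d
  P <- (a * A + b * B) / p
  Q <- (c_ * C + d * D) / q
  t <- p * q / (p + q) * sum((P - Q)^2)
  2 * pi^2.5 / (p * q * sqrt(p + q)) *
    exp(-a * b / p * sum((A - B)^2) - c_ * d / q * sum((C - D)^2)) *
    boys_f0(t)
}

#' Compute integrals over contracted s-type Gaussians
#'
#' @param geom a `geometry`
#' @param basis_spec per-element list of shells (see [basis_sto3g()])
#' @return object of class `integral_set` with fields `overlap`, `hcore`,
#'   `eri` (n^4 array, chemists' notation), `dipole_ops` (three matrices of
#'   electronic position integrals), `nuclear_repulsion`, `basis_centers`,
#'   and internal provider data used for embedding operators and forces.
#' @export
gaussian_integrals <- function(geom, basis_spec) {
  funs <- .expand_basis(geom, basis_spec)
  n <- length(funs)
  S <- matrix(0, n, n); Tm <- matrix(0, n, n); V <- matrix(0, n, n)
  dip <- list(matrix(0, n, n), matrix(0, n, n), matrix(0, n, n))
  for (i in seq_len(n)) {
    for (j in seq_len(i)) {
      S[i, j] <- S[j, i] <- .contr_pair(funs[[i]], funs[[j]], .prim_overlap)
      Tm[i, j] <- Tm[j, i] <- .contr_pair(funs[[i]], funs[[j]], .prim_kinetic)
      va <- 0
      for (a in seq_along(geom$symbols)) {
        va <- va - geom$charges[a] *
          .contr_pair(funs[[i]], funs[[j]], .prim_attraction,
                      C = geom$coords[a, ])
      }
      V[i, j] <- V[j, i] <- va
      for (comp in 1:3) {
        dip[[comp]][i, j] <- dip[[comp]][j, i] <-
          .contr_pair2(funs[[i]], funs[[j]], comp)
      }
    }
  }
  eri <- array(0, c(n, n, n, n))
  # unique (ij|kl) under 8-fold symmetry
  for (i in seq_len(n)) for (j in seq_len(i)) {
    ij <- i * (i - 1) / 2 + j
    for (k in seq_len(n)) for (l in seq_len(k)) {
      kl <- k * (k - 1) / 2 + l
      if (kl > ij) next
      val <- 0
      fi <- funs[[i]]; fj <- funs[[j]]; fk <- funs[[k]]; fl <- funs[[l]]
      for (pi_ in seq_along(fi$expo)) for (pj in seq_along(fj$expo))
        for (pk in seq_along(fk$expo)) for (pl in seq_along(fl$expo)) {
          val <- val + fi$coef[pi_] * fj$coef[pj] * fk$coef[pk] * fl$coef[pl] *
            .prim_eri(fi$expo[pi_], fi$center, fj$expo[pj], fj$center,
                      fk$expo[pk], fk$center, fl$expo[pl], fl$center)
        }
      for (idx in list(c(i, j, k, l), c(j, i, k, l), c(i, j, l, k),
                       c(j, i, l, k), c(k, l, i, j), c(l, k, i, j),
                       c(k, l, j, i), c(l, k, j, i))) {
        eri[idx[1], idx[2], idx[3], idx[4]] <- val
      }
    }
  }
  enuc <- 0
  na <- length(geom$symbols)
  if (na > 1) {
    for (a in 2:na) for (b in seq_len(a - 1)) {
      enuc <- enuc + geom$charges[a] * geom$charges[b] /
        sqrt(sum((geom$coords[a, ] - geom$coords[b, ])^2))
    }
  }
  integral_set(overlap = S, hcore = Tm + V, eri = eri, dipole_ops = dip,
               nuclear_repulsion = enuc,
               basis_centers = vapply(funs, function(f) f$atom, 1L),
               provider = "gaussian",
               provider_data = list(funs = funs, geom = geom,
                                    basis_spec = basis_spec))
}

.contr_pair2 <- function(fa, fb, comp) {
  acc <- 0
  for (i in seq_along(fa$expo)) for (j in seq_along(fb$expo)) {
    acc <- acc + fa$coef[i] * fb$coef[j] *
      .prim_dipole(fa$expo[i], fa$center, fb$expo[j], fb$center, comp)
  }
  acc
}

# matrix of attraction integrals <i| 1/|r - C| |j> (positive kernel)
attraction_matrix <- function(integrals, C) {
  funs <- integrals$provider_data$funs
  n <- length(funs)
  M <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(i)) {
    M[i, j] <- M[j, i] <- .contr_pair(funs[[i]], funs[[j]],
                                      .prim_attraction, C = C)
  }
  M
}

# gradient of attraction_matrix w.r.t. C: list of three matrices
attraction_matrix_grad <- function(integrals, C) {
  funs <- integrals$provider_data$funs
  n <- length(funs)
  G <- list(matrix(0, n, n), matrix(0, n, n), matrix(0, n, n))
  for (i in seq_len(n)) for (j in seq_len(i)) {
    g <- c(0, 0, 0)
    fi <- funs[[i]]; fj <- funs[[j]]
    for (pi_ in seq_along(fi$expo)) for (pj in seq_along(fj$expo)) {
      g <- g + fi$coef[pi_] * fj$coef[pj] *
        .prim_attraction_grad(fi$expo[pi_], fi$center,
                              fj$expo[pj], fj$center, C)
    }
    for (comp in 1:3) G[[comp]][i, j] <- G[[comp]][j, i] <- g[comp]
  }
  G
}

#' Assemble an integral set
#'
#' Shared container for both providers; validates the integral-symmetry
#' invariants (symmetric positive-definite overlap, 8-fold ERI symmetry).
#'
#' @param overlap,hcore n x n symmetric matrices
#' @param eri n^4 array in chemists' notation
#' @param dipole_ops list of three n x n electronic position matrices
#' @param nuclear_repulsion scalar (hartree)
#' @param basis_centers atom index of each basis function
#' @param provider `"gaussian"` or `"ppp"`
#' @param provider_data provider internals (basis functions or PPP params)
#' @return object of class `integral_set`
#' @export
integral_set <- function(overlap, hcore, eri, dipole_ops, nuclear_repulsion,
                         basis_centers, provider, provider_data = list()) {
  n <- nrow(overlap)
  ev <- eigen(overlap, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) stop("integral_set: overlap not positive definite")
  stopifnot(max(abs(overlap - t(overlap))) < 1e-12,
            max(abs(hcore - t(hcore))) < 1e-12)
  # precompute matricized ERI for Fock builds: J uses (ij|kl), K uses (ik|jl)
  eriJ <- matrix(eri, n * n, n * n)
  eriK <- matrix(aperm(eri, c(1, 3, 2, 4)), n * n, n * n)
  structure(list(overlap = overlap, hcore = hcore, eri = eri,
                 eriJ = eriJ, eriK = eriK, dipole_ops = dipole_ops,
                 nuclear_repulsion = nuclear_repulsion,
                 basis_centers = as.integer(basis_centers),
                 n_basis = n, provider = provider,
                 provider_data = provider_data),
            class = "integral_set")
}

#' @export
print.integral_set <- function(x, ...) {
  cat(sprintf("<integral_set: %d basis functions, provider %s, Vnn %.8f>\n",
              x$n_basis, x$provider, x$nuclear_repulsion))
  invisible(x)
}
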