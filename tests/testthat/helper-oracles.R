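# Independent oracles, deliberately coded along different routes than the
# package implementation: plain-loop Fock builds with damped fixed-point
# SCF (no DIIS), a Fock-space (occupation-number-vector) exact
# diagonalization, and direct determinant-energy evaluation.

# ---- textbook SCF oracle --------------------------------------------------

oracle_fock_loops <- function(h, eri, da, db) {
  n <- nrow(h)
  fa <- h; fb <- h
  for (i in 1:n) for (j in 1:n) {
    jij <- 0; kija <- 0; kijb <- 0
    for (k in 1:n) for (l in 1:n) {
      jij <- jij + eri[i, j, k, l] * (da[k, l] + db[k, l])
      kija <- kija + eri[i, k, j, l] * da[k, l]
      kijb <- kijb + eri[i, k, j, l] * db[k, l]
    }
    fa[i, j] <- h[i, j] + jij - kija
    fb[i, j] <- h[i, j] + jij - kijb
  }
  list(fa = fa, fb = fb)
}

oracle_energy <- function(h, eri, da, db, enuc) {
  f <- oracle_fock_loops(h, eri, da, db)
  0.5 * (sum((da + db) * h) + sum(da * f$fa) + sum(db * f$fb)) + enuc
}

# damped Roothaan fixed point; guess from hcore; optional alpha-spin
# perturbation to break symmetry
oracle_scf <- function(ints, n_alpha, n_beta, restricted = TRUE,
                       max_iter = 3000, damp = 0.3, mix = 0) {
  S <- ints$overlap; h <- ints$hcore; eri <- ints$eri
  n <- nrow(S)
  es <- eigen(S, symmetric = TRUE)
  X <- es$vectors %*% (t(es$vectors) / sqrt(es$values))
  diag_occ <- function(F, nocc, perturb = 0) {
    fo <- t(X) %*% F %*% X
    if (perturb != 0) fo <- fo + perturb * diag(seq_len(n)) * 1e-3
    e <- eigen((fo + t(fo)) / 2, symmetric = TRUE)
    ord <- order(e$values)
    C <- X %*% e$vectors[, ord, drop = FALSE]
    Co <- C[, seq_len(nocc), drop = FALSE]
    Co %*% t(Co)
  }
  da <- diag_occ(h, n_alpha, perturb = mix)
  db <- diag_occ(h, n_beta)
  e_old <- Inf
  for (it in seq_len(max_iter)) {
    f <- oracle_fock_loops(h, eri, da, db)
    e <- oracle_energy(h, eri, da, db, ints$nuclear_repulsion)
    da_new <- diag_occ(f$fa, n_alpha)
    db_new <- if (restricted) da_new else diag_occ(f$fb, n_beta)
    da <- (1 - damp) * da_new + damp * da
    db <- (1 - damp) * db_new + damp * db
    if (abs(e - e_old) < 1e-12 && it > 5) break
    e_old <- e
  }
  list(energy = e, da = da, db = db)
}

# ---- Fock-space exact diagonalization oracle ------------------------------
# Jordan-Wigner creation operators over 2n spin orbitals (alpha block
# first); dimension 4^n, usable for n <= 4.

oracle_fock_space_fci <- function(ints, n_alpha, n_beta, n_lowest = 4) {
  n <- ints$n_basis
  es <- eigen(ints$overlap, symmetric = TRUE)
  X <- es$vectors %*% (t(es$vectors) / sqrt(es$values))
  h <- t(X) %*% ints$hcore %*% X
  g <- ints$eri
  for (leg in 1:4) {
    g <- aperm(g, c(2, 3, 4, 1))
    g <- array(matrix(g, n^3, n) %*% X, c(n, n, n, n))
  }
  m <- 2 * n
  dim_f <- 2^m
  # bit p of (state-1) = occupation of spin orbital p (1-based)
  occbit <- function(state, p) bitwAnd(bitwShiftR(state - 1L, p - 1L), 1L)
  # creation operator matrices as sparse-ish index vectors
  cre <- vector("list", m)
  for (p in 1:m) {
    from <- integer(0); to <- integer(0); sgn <- numeric(0)
    for (s in seq_len(dim_f)) {
      if (occbit(s, p) == 0L) {
        nb <- 0L
        if (p > 1) for (q in 1:(p - 1)) nb <- nb + occbit(s, q)
        from <- c(from, s)
        to <- c(to, s + bitwShiftL(1L, p - 1L))
        sgn <- c(sgn, (-1)^nb)
      }
    }
    M <- matrix(0, dim_f, dim_f)
    M[cbind(to, from)] <- sgn
    cre[[p]] <- M
  }
  ann <- lapply(cre, t)
  so <- function(p, spin) if (spin == 1) p else n + p
  H <- matrix(0, dim_f, dim_f)
  for (sp in 1:2) {
    for (p in 1:n) for (q in 1:n) {
      if (h[p, q] != 0) {
        H <- H + h[p, q] * cre[[so(p, sp)]] %*% ann[[so(q, sp)]]
      }
    }
  }
  for (s1 in 1:2) for (s2 in 1:2) {
    for (p in 1:n) for (q in 1:n) for (r in 1:n) for (ss in 1:n) {
      gv <- g[p, q, r, ss]
      if (gv != 0) {
        H <- H + 0.5 * gv * cre[[so(p, s1)]] %*% cre[[so(r, s2)]] %*%
          ann[[so(ss, s2)]] %*% ann[[so(q, s1)]]
      }
    }
  }
  # restrict to the (n_alpha, n_beta) sector
  na_of <- function(s) sum(vapply(1:n, function(p) occbit(s, p), 0L))
  nb_of <- function(s) sum(vapply((n + 1):m, function(p) occbit(s, p), 0L))
  sel <- which(vapply(seq_len(dim_f), na_of, 0L) == n_alpha &
                 vapply(seq_len(dim_f), nb_of, 0L) == n_beta)
  Hs <- H[sel, sel, drop = FALSE]
  ev <- sort(eigen((Hs + t(Hs)) / 2, symmetric = TRUE,
                   only.values = TRUE)$values)
  ev[seq_len(min(n_lowest, length(ev)))] + ints$nuclear_repulsion
}

# ---- direct determinant-energy oracle -------------------------------------
# <det|H|det> for occupied AO-basis orbitals, plain Slater rules

oracle_determinant_energy <- function(ints, c_occ_a, c_occ_b) {
  h <- ints$hcore; eri <- ints$eri
  da <- c_occ_a %*% t(c_occ_a)
  db <- c_occ_b %*% t(c_occ_b)
  n <- nrow(h)
  e1 <- sum((da + db) * h)
  e2 <- 0
  for (i in 1:n) for (j in 1:n) for (k in 1:n) for (l in 1:n) {
    dt_ij <- da[i, j] + db[i, j]
    dt_kl <- da[k, l] + db[k, l]
    e2 <- e2 + 0.5 * eri[i, j, k, l] * dt_ij * dt_kl
    e2 <- e2 - 0.5 * eri[i, k, j, l] *
      (da[i, j] * da[k, l] + db[i, j] * db[k, l])
  }
  e1 + e2 + ints$nuclear_repulsion
}

# numerical gradient of a scalar function of a 3-vector
oracle_num_grad <- function(fn, x, h = 1e-5) {
  vapply(1:3, function(c_) {
    xp <- x; xp[c_] <- xp[c_] + h
    xm <- x; xm[c_] <- xm[c_] - h
    (fn(xp) - fn(xm)) / (2 * h)
  }, 0)
}
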