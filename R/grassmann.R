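#' @title Grassmann-manifold density-matrix extrapolation
#' @name grassmann_extrapolation
#' @description
#' SCF guess acceleration along a trajectory.  Idempotent density matrices
#' of fixed trace live on a Grassmann manifold; mapping them to the tangent
#' space at a reference point turns extrapolation into ordinary linear
#' algebra, and mapping back guarantees the guess is again idempotent with
#' exact integer trace (no purification needed).  Extrapolation
#' coefficients are fitted on a Coulomb-matrix geometry descriptor; for
#' open shells the alpha and beta densities are extrapolated independently
#' with the same (single-descriptor) coefficients.
NULL

#' Logarithmic map: density matrix to tangent space
#'
#' For an idempotent orthonormal-basis density `D` with occupied orbitals
#' `C`, computes `L = (I - C0 t(C0)) C solve(t(C0) C)` and returns
#' `Gamma = U atan(S) t(V)` from the thin SVD of `L`; the singular values
#' of `Gamma` are the principal angles between the two occupied spaces.
#'
#' @param density idempotent orthonormal-basis density matrix
#' @param c0 reference occupied orbitals (orthonormal columns)
#' @return tangent matrix `Gamma` (n x n_occ) with `t(c0) Gamma = 0`
#' @export
grassmann_log <- function(density, c0) {
  k <- ncol(c0)
  e <- eigen((density + t(density)) / 2, symmetric = TRUE)
  C <- e$vectors[, seq_len(k), drop = FALSE]   # eigenvalues ~ 1 first
  if (any(e$values[seq_len(k)] < 0.5)) {
    stop("grassmann_log: density is not idempotent with trace ", k)
  }
  ov <- t(c0) %*% C
  d <- abs(det(ov))
  if (d < 1e-10) stop("grassmann_log: reference too far (occupied space ",
                      "nearly orthogonal to the reference)")
  L <- (C - c0 %*% (t(c0) %*% C)) %*% solve(ov)
  sv <- svd(L, nu = k, nv = k)
  sv$u %*% (atan(sv$d) * t(sv$v))
}

#' Exponential map: tangent matrix back to an idempotent density
#'
#' From the thin SVD `Gamma = U S t(V)`, builds
#' `C = (c0 V cos(S) + U sin(S)) t(V)` and returns `D = C t(C)`, which is
#' idempotent with exact trace `ncol(c0)` by construction.
#'
#' @param gamma tangent matrix (n x n_occ) with `t(c0) gamma = 0` to 1e-8
#' @param c0 reference occupied orbitals
#' @return orthonormal-basis density matrix
#' @export
grassmann_exp <- function(gamma, c0) {
  k <- ncol(c0)
  if (max(abs(t(c0) %*% gamma)) > 1e-8) {
    stop("grassmann_exp: tangent matrix violates horizontality")
  }
  sv <- svd(gamma, nu = k, nv = k)
  C <- (c0 %*% sv$v %*% diag(cos(sv$d), k) +
          sv$u %*% diag(sin(sv$d), k)) %*% t(sv$v)
  C %*% t(C)
}

#' Coulomb-matrix geometry descriptor
#'
#' `M_IJ = Z_I Z_J / r_IJ` off-diagonal and `M_II = 0.5 Z_I^2.4`, flattened
#' upper triangle (diagonal included) in fixed atom order -- atom identity
#' is stable along one trajectory, and sorting would break smoothness.
#'
#' @param geom a `geometry`
#' @return numeric descriptor vector
#' @export
coulomb_descriptor <- function(geom) {
  z <- geom$charges
  n <- length(z)
  M <- diag(0.5 * z^2.4, n)
  if (n > 1) {
    for (i in 2:n) for (j in seq_len(i - 1)) {
      r <- sqrt(sum((geom$coords[i, ] - geom$coords[j, ])^2))
      if (r < 1e-8) stop("coulomb_descriptor: coincident atoms")
      M[i, j] <- M[j, i] <- z[i] * z[j] / r
    }
  }
  M[upper.tri(M, diag = TRUE)]
}

#' Fit extrapolation coefficients on descriptors
#'
#' Ridge-regularized least squares:
#' `c = argmin ||d_now - sum_k c_k d_k||^2 + lambda ||c||^2`.
#' The tiny ridge keeps the normal equations solvable for near-collinear
#' histories (small time steps); coefficients are NOT constrained to sum
#' to one.
#'
#' @param descriptors list of history descriptor vectors
#' @param d_now descriptor at the current geometry
#' @param lambda ridge parameter (default 1e-10)
#' @return coefficient vector, one per history entry
#' @export
fit_coefficients <- function(descriptors, d_now, lambda = 1e-10) {
  Dm <- do.call(cbind, descriptors)
  G <- crossprod(Dm) + lambda * diag(ncol(Dm))
  as.vector(solve(G, crossprod(Dm, d_now)))
}

#' Create an extrapolation history
#'
#' Ring buffers of per-spin tangent matrices and geometry descriptors with
#' a fixed tangent-space base point per window.  When the newest converged
#' density drifts more than `reset_angle` (largest principal angle,
#' radians) from the base point, the window resets with a new reference.
#'
#' @param capacity history depth M (default 6)
#' @param overlap AO overlap of the system (fixes the orthonormal basis)
#' @param reset_angle drift threshold in radians (default 1)
#' @param ridge_lambda ridge parameter for the coefficient fit
#' @return an environment of class `extrapolation_history`
#' @export
extrapolation_history <- function(capacity = 6, overlap, reset_angle = 1.0,
                                  ridge_lambda = 1e-10) {
  h <- new.env(parent = emptyenv())
  h$capacity <- capacity
  h$reset_angle <- reset_angle
  h$ridge_lambda <- ridge_lambda
  h$X <- lowdin_transform(overlap)
  h$Shalf <- .sqrtm(overlap)
  h$c0_alpha <- NULL
  h$c0_beta <- NULL
  h$gam_alpha <- list()
  h$gam_beta <- list()
  h$desc <- list()
  class(h) <- c("extrapolation_history", "environment")
  h
}

#' Number of stored history entries
#' @param history an `extrapolation_history`
#' @return integer
#' @export
history_length <- function(history) length(history$desc)

# occupied orbitals of an orthonormal-basis density
.occ_orbitals <- function(D) {
  k <- round(sum(diag(D)))
  e <- eigen((D + t(D)) / 2, symmetric = TRUE)
  e$vectors[, seq_len(k), drop = FALSE]
}

#' Push a converged density into the history
#'
#' Converts the AO density to the orthonormal basis, logs both spin
#' densities at the window's base point and stores them with the geometry
#' descriptor.  A drift beyond the reset angle clears the window and
#' restarts it at the current density (logged).
#'
#' @param history an `extrapolation_history`
#' @param density converged `spin_density_pair` (AO)
#' @param geom the `geometry` the density belongs to
#' @return the history, invisibly
#' @export
history_push <- function(history, density, geom) {
  Don_a <- history$Shalf %*% density$d_alpha %*% history$Shalf
  Don_b <- history$Shalf %*% density$d_beta %*% history$Shalf
  if (is.null(history$c0_alpha)) {
    history$c0_alpha <- .occ_orbitals(Don_a)
    history$c0_beta <- .occ_orbitals(Don_b)
  }
  ga <- try(grassmann_log(Don_a, history$c0_alpha), silent = TRUE)
  gb <- try(grassmann_log(Don_b, history$c0_beta), silent = TRUE)
  # singular values of the tangent matrix are the principal angles (rad)
  drift <- if (inherits(ga, "try-error") || inherits(gb, "try-error")) {
    Inf
  } else {
    max(svd(ga, nu = 0, nv = 0)$d[1], svd(gb, nu = 0, nv = 0)$d[1])
  }
  if (drift > history$reset_angle || !is.finite(drift)) {
    log_line("info", "Grassmann history reset: reference drift ",
             sprintf("%.3f", drift), " rad")
    history$c0_alpha <- .occ_orbitals(Don_a)
    history$c0_beta <- .occ_orbitals(Don_b)
    history$gam_alpha <- list()
    history$gam_beta <- list()
    history$desc <- list()
    ga <- grassmann_log(Don_a, history$c0_alpha)
    gb <- grassmann_log(Don_b, history$c0_beta)
  }
  history$gam_alpha <- c(history$gam_alpha, list(ga))
  history$gam_beta <- c(history$gam_beta, list(gb))
  history$desc <- c(history$desc, list(coulomb_descriptor(geom)))
  if (length(history$desc) > history$capacity) {
    history$gam_alpha <- history$gam_alpha[-1]
    history$gam_beta <- history$gam_beta[-1]
    history$desc <- history$desc[-1]
  }
  invisible(history)
}

#' Extrapolate a guess density for a new geometry
#'
#' Fits coefficients on the Coulomb descriptors (one shared set for both
#' spins), combines the stored tangent matrices linearly and maps back to
#' the manifold; the result is idempotent with exact per-spin traces.
#'
#' @param history an `extrapolation_history` with at least 2 entries
#' @param geom the new `geometry`
#' @return AO-basis `spin_density_pair` guess
#' @export
extrapolate_guess <- function(history, geom) {
  m <- history_length(history)
  if (m < 2) stop("extrapolate_guess: need at least 2 history entries")
  cf <- fit_coefficients(history$desc, coulomb_descriptor(geom),
                         lambda = history$ridge_lambda)
  ga <- 0; gb <- 0
  for (k in seq_len(m)) {
    ga <- ga + cf[k] * history$gam_alpha[[k]]
    gb <- gb + cf[k] * history$gam_beta[[k]]
  }
  Don_a <- grassmann_exp(ga, history$c0_alpha)
  Don_b <- grassmann_exp(gb, history$c0_beta)
  X <- history$X
  spin_density_pair(X %*% Don_a %*% t(X), X %*% Don_b %*% t(X))
}
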