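# shared fixtures, built once per test run

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

get_toy <- function() cached("toy", function() make_pcet_toy(seed = 1))

get_toy_gas <- function() {
  cached("toy_gas", function() make_pcet_toy(seed = 1, env_n_sites = 0))
}

get_h2_ints <- function() {
  cached("h2", function() {
    m <- make_small_molecule("h2")
    gaussian_integrals(m$geometry, m$basis)
  })
}

get_toy_states <- function() {
  cached("toy_states", function() {
    toy <- get_toy()
    ctx <- embedding_context(toy$sites)
    ints <- ppp_integrals(toy$geometry, toy$params)
    ne <- toy$params$electrons
    gs <- scf_solve(ints, ne / 2, ne / 2, mode = "restricted",
                    embedding = ctx, control = scf_control(max_cycles = 400))
    ct <- deltascf_solve(ints, toy$excitation, gs, method = "imom",
                         embedding = ctx,
                         control = scf_control(max_cycles = 400))
    list(toy = toy, ctx = ctx, ints = ints, gs = gs, ct = ct)
  })
}

make_random_sites <- function(n, seed = 7, all_pol = TRUE) {
  set.seed(seed)
  quad <- array(0, c(n, 3, 3))
  for (i in 1:n) {
    m <- matrix(rnorm(9, sd = 0.05), 3, 3); m <- (m + t(m)) / 2
    quad[i, , ] <- m - diag(3) * sum(diag(m)) / 3
  }
  embedding_sites(matrix(rnorm(3 * n, sd = 8), n, 3),
                  charge = rnorm(n, sd = 0.2),
                  dipole = matrix(rnorm(3 * n, sd = 0.1), n, 3),
                  quadrupole = quad, alpha = runif(n, 1, 6),
                  polarizable = rep(all_pol, n), group = seq_len(n))
}
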