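# Shared fixtures: random valid parameter sets and an independent oracle for
# the restricted desired-gains index.

# Random panel + PSD genetic parameters with heritabilities in (0, 1).
random_params <- function(n, seed) {
  set.seed(seed)
  traits <- paste0("t", seq_len(n))
  panel <- trait_panel(traits, rep("u", n),
                       means = runif(n, 10, 100), reference = traits[1L])
  A <- matrix(rnorm(n * n), n)
  G <- crossprod(A) / n + diag(0.05, n)
  B <- matrix(rnorm(n * n), n)
  E <- crossprod(B) / n + diag(0.05, n)
  dimnames(G) <- dimnames(E) <- list(traits, traits)
  list(panel = panel, params = genetic_parameters(panel, G, G + E))
}

# Independent oracle for min b'Pb subject to G*'b = Q: direct solve of the
# KKT system [2P G*; G*' 0] [b; lambda] = [0; Q]. A different code path from
# the nested solves in restricted_gain_weights().
kkt_oracle <- function(P, Gstar, Q) {
  n <- nrow(P)
  m <- ncol(Gstar)
  K <- rbind(cbind(2 * P, Gstar),
             cbind(t(Gstar), matrix(0, m, m)))
  sol <- solve(K, c(rep(0, n), Q))
  unname(sol[seq_len(n)])
}

# 2x2 worked instance used across tests
two_trait_params <- function() {
  panel <- trait_panel(c("t1", "t2"), c("u", "u"), c(10, 20),
                       reference = "t1")
  G <- matrix(c(0.4, 0.1, 0.1, 0.3), 2, 2,
              dimnames = list(panel$name, panel$name))
  P <- matrix(c(1, 0.5, 0.5, 1), 2, 2,
              dimnames = list(panel$name, panel$name))
  list(panel = panel, params = genetic_parameters(panel, G, P))
}

# random PSD correlation matrix
nearest_r <- function(n) {
  A <- matrix(rnorm(n * n), n)
  stats::cov2cor(crossprod(A) + diag(n))
}

identity_params <- function(n = 2L, reference = NULL) {
  traits <- paste0("t", seq_len(n))
  if (is.null(reference)) reference <- traits[1L]
  panel <- trait_panel(traits, rep("u", n), rep(1, n),
                       reference = reference)
  I <- diag(n)
  dimnames(I) <- list(traits, traits)
  list(panel = panel, params = genetic_parameters(panel, I, I))
}
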