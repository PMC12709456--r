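# Shared fixtures, built in code.

# Directed path 1 -> 2 -> ... -> n with unit weights.
chain_coupling <- function(n) {
  C <- matrix(0, n, n)
  C[cbind(seq_len(n - 1), 2:n)] <- 1
  C
}

# Random sparse nonnegative directed network, weakly connected by
# construction (a chain backbone plus random extra edges).
random_network <- function(n, extra = n, seed = 1, wmax = 1) {
  set.seed(seed)
  C <- chain_coupling(n)
  C[cbind(seq_len(n - 1), 2:n)] <- runif(n - 1, 0.5, wmax)
  for (k in seq_len(extra)) {
    ij <- sample(n, 2)
    C[ij[1], ij[2]] <- runif(1, 0.1, wmax)
  }
  diag(C) <- 0
  C
}

# Small stable coupling + parameters for linearized-model tests.
small_hopf_system <- function(n = 4, seed = 1) {
  set.seed(seed)
  C <- matrix(0, n, n)
  C[upper.tri(C)] <- runif(sum(upper.tri(C)), 0, 0.08)
  C[lower.tri(C)] <- runif(sum(lower.tri(C)), 0, 0.03)
  diag(C) <- 0
  list(C = C,
       params = hopf_params(a = rep(-0.1, n),
                            omega = 2 * pi * runif(n, 0.02, 0.06),
                            sigma = 0.02))
}

# Independent oracle: trophic incoherence minimized directly over levels
# (gradient-free), for comparison against the Laplacian solve.
minimize_incoherence <- function(C) {
  n <- nrow(C)
  obj <- function(h) {
    res2 <- (outer(h, h, "-") - 1)^2
    sum(C * res2) / sum(C)
  }
  fit <- optim(rep(0, n), obj, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  fit$value
}
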