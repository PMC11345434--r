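# Shared builders for small test systems.

# single uncoupled node
one_node <- function(a, f = 1, beta = 0, G = 0) {
  list(params = oscillator_params(a = a, f = f, beta = beta, G = G, n = 1),
       C = coupling_matrix(matrix(0, 1, 1)))
}

# two nodes with a single directed link 1 -> 2 of weight w
two_node_chain <- function(w = 0.05, a = -0.02, f = c(1, 1), beta = 0.02,
                           G = 1) {
  list(params = oscillator_params(a = a, f = f, beta = beta, G = G, n = 2),
       C = coupling_matrix(rbind(c(0, 0), c(w, 0))))
}

# random sparse nonnegative coupling matrix with given density
random_sparse_coupling <- function(n, density, seed, lo = 0.02, hi = 0.08) {
  set.seed(seed)
  C <- matrix(0, n, n)
  k <- round(density * n * (n - 1))
  idx <- sample(which(row(C) != col(C)), k)
  C[idx] <- runif(k, lo, hi)
  coupling_matrix(C)
}

# the canonical study working point used for synthetic experiments:
# strong diffusive coupling so that regional integration timescales are tens
# of milliseconds (cortex-like) and moments are estimable from short series
study_params <- function(n, seed, a = -5, G = 150, beta = 0.02,
                         region_ids = NULL) {
  set.seed(seed)
  oscillator_params(a = a, f = runif(n, 0.5, 2), G = G, beta = beta,
                    region_ids = region_ids, n = n)
}

offdiag_v <- function(m) m[row(m) != col(m)]
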