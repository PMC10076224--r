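# Independent reference implementations used only to check the package's
# fast paths. Deliberately naive: dense algebra and exhaustive enumeration.

# log density of (y_i, y_j) under Sigma1 (x) K + D (x) I via the dense
# 2n x 2n Cholesky factorisation
dense_pair_loglik <- function(y_i, y_j, coords, params, jitter = 1e-6) {
  n <- nrow(coords)
  K <- sq_exp_kernel(coords, params$length_scale)
  diag(K) <- diag(K) + jitter
  A <- matrix(c(params$a1, params$a2, 0, params$a3), 2, 2)
  S1 <- A %*% t(A)
  cov <- kronecker(S1, K) +
    kronecker(diag(c(params$noise_i, params$noise_j)), diag(n))
  L <- t(chol(cov))
  v <- forwardsolve(L, c(y_i, y_j))
  -n * log(2 * pi) - sum(log(diag(L))) - 0.5 * sum(v^2)
}

# single-state GP log density: y ~ N(0, s * K + d * I)
dense_single_loglik <- function(y, coords, s, d, length_scale, jitter = 1e-6) {
  n <- nrow(coords)
  K <- sq_exp_kernel(coords, length_scale)
  diag(K) <- diag(K) + jitter
  cov <- s * K + d * diag(n)
  L <- t(chol(cov))
  v <- forwardsolve(L, y)
  -n / 2 * log(2 * pi) - sum(log(diag(L))) - 0.5 * sum(v^2)
}

# decode a Pruefer sequence into the edge list of a labeled tree on k nodes
prufer_decode <- function(seq, k) {
  deg <- tabulate(seq, k) + 1
  edges <- matrix(0L, k - 1, 2)
  for (i in seq_along(seq)) {
    leaf <- which(deg == 1)[1]
    edges[i, ] <- c(leaf, seq[i])
    deg[leaf] <- 0L
    deg[seq[i]] <- deg[seq[i]] - 1L
  }
  edges[k - 1, ] <- which(deg == 1)
  edges
}

# maximum spanning-tree weight by exhaustive enumeration over all k^(k-2)
# labeled trees (Cayley)
brute_force_mst_weight <- function(W) {
  k <- nrow(W)
  seqs <- as.matrix(expand.grid(rep(list(seq_len(k)), k - 2)))
  best <- -Inf
  for (r in seq_len(nrow(seqs))) {
    e <- prufer_decode(seqs[r, ], k)
    best <- max(best, sum(W[e]))
  }
  best
}

# random symmetric weight matrix in [0,1] with zero diagonal
random_state_matrix <- function(k, states = paste0("s", seq_len(k))) {
  m <- matrix(0, k, k, dimnames = list(states, states))
  m[upper.tri(m)] <- stats::runif(k * (k - 1) / 2)
  m + t(m)
}

# build a storder_tree directly from an edge tibble
read_tree_from_edges <- function(edges) {
  structure(list(states = sort(unique(c(edges$state_a, edges$state_b))),
                 edges = edges, total_weight = sum(edges$weight),
                 weakly_connected = FALSE),
            class = "storder_tree")
}

# small random pair-GP parameter set
random_gp_params <- function() {
  list(a1 = stats::runif(1, 0.2, 2), a2 = stats::runif(1, -1, 1),
       a3 = stats::runif(1, 0.2, 2), noise_i = stats::runif(1, 0.05, 1),
       noise_j = stats::runif(1, 0.05, 1),
       length_scale = stats::runif(1, 0.3, 3))
}
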