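# Independent brute-force correspondence oracle: forms the residual matrix
# explicitly, element by element, and decomposes its cross-product with
# eigen().  Shares no code path with run_mca (which sweeps and uses svd).

oracle_mca <- function(Z) {
  N <- sum(Z)
  P <- Z / N
  r <- rowSums(P)
  cm <- colSums(P)
  R <- matrix(0, nrow(Z), ncol(Z))
  for (i in seq_len(nrow(Z))) {
    for (j in seq_len(ncol(Z))) {
      e <- r[i] * cm[j]
      R[i, j] <- (P[i, j] - e) / sqrt(e)
    }
  }
  M <- t(R) %*% R
  ev <- eigen(M, symmetric = TRUE)
  lambda <- pmax(ev$values, 0)
  # principal coordinates and contributions from the eigenvectors of M
  K <- sum(lambda > 1e-10)
  G <- matrix(0, ncol(Z), K)
  ctr <- matrix(0, ncol(Z), K)
  for (k in seq_len(K)) {
    for (j in seq_len(ncol(Z))) {
      G[j, k] <- ev$vectors[j, k] / sqrt(cm[j]) * sqrt(lambda[k])
      ctr[j, k] <- cm[j] * G[j, k]^2 / lambda[k]
    }
  }
  list(eigenvalues = lambda[seq_len(K)], coords = G, contrib = ctr,
       total_inertia = sum(lambda))
}

# random 0/1 marker matrix with no constant column
random_marker_matrix <- function(n, q) {
  repeat {
    m <- matrix(rbinom(n * q, 1L, runif(q, 0.2, 0.8)[rep(1:q, each = n)]),
                n, q, dimnames = list(NULL, sprintf("v%02d", 1:q)))
    cs <- colSums(m)
    if (all(cs > 0L & cs < n) && qr(m)$rank > 1L) return(m)
  }
}
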