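# Independent oracles used to check the package's model-fitting paths.

# Dense Henderson mixed-model-equation solve at fixed variance components for
# y = X beta + Zb b + a + sa + e. Independent of the package's V-space
# projection route: it inverts the kernel and builds the full coefficient
# matrix explicitly.
mme_oracle <- function(y, X, Zb, K, site, theta) {
  n <- length(y)
  sites <- sort(unique(site))
  Kinv <- solve(K)
  # site x additive: one effect per (site, individual) cell
  Z3 <- matrix(0, n, length(sites) * n)
  for (i in seq_len(n)) {
    Z3[i, (match(site[i], sites) - 1L) * n + i] <- 1
  }
  Ginv_blocks <- list(diag(1 / theta["s2_b"], ncol(Zb)),
                      Kinv / theta["s2_a"],
                      kronecker(diag(length(sites)), Kinv) / theta["s2_sa"])
  Z <- cbind(Zb, diag(n), Z3)
  Ginv <- matrix(0, ncol(Z), ncol(Z))
  o <- 0
  for (B in Ginv_blocks) {
    idx <- o + seq_len(nrow(B))
    Ginv[idx, idx] <- B
    o <- o + nrow(B)
  }
  s2e <- theta["s2_e"]
  C <- rbind(cbind(crossprod(X), crossprod(X, Z)),
             cbind(crossprod(Z, X), crossprod(Z) + s2e * Ginv)) / s2e
  rhs <- c(crossprod(X, y), crossprod(Z, y)) / s2e
  sol <- solve(C, rhs)
  nb <- ncol(Zb)
  list(beta = sol[seq_len(ncol(X))],
       b = sol[ncol(X) + seq_len(nb)],
       a = sol[ncol(X) + nb + seq_len(n)])
}

# joint ridge solve for y = W theta + Z a + e with a ~ N(0, s2m I) and an
# essentially flat prior on theta (precision 1e-10, matching the sampler)
ridge_oracle <- function(y, W, Z, s2m, s2e) {
  q <- ncol(W); m <- ncol(Z)
  C <- rbind(cbind(crossprod(W) / s2e + diag(1e-10, q), crossprod(W, Z) / s2e),
             cbind(crossprod(Z, W) / s2e, crossprod(Z) / s2e + diag(1 / s2m, m)))
  rhs <- c(crossprod(W, y), crossprod(Z, y)) / s2e
  sol <- solve(C, rhs)
  list(theta = sol[seq_len(q)], a = sol[q + seq_len(m)])
}

# batch-means Monte-Carlo standard error of a chain's mean
mcse <- function(x, n_batches = 25L) {
  n <- length(x)
  bs <- floor(n / n_batches)
  means <- vapply(seq_len(n_batches), function(b) {
    mean(x[((b - 1L) * bs + 1L):(b * bs)])
  }, 0)
  sd(means) / sqrt(n_batches)
}
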