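# Independent reference implementations used as oracles. These deliberately
# share no code with the package internals: explicit design matrices and
# qr-based least squares instead of Gram/Hadamard shortcuts.

# plain cosine, the brute-force counterpart of tucker_congruence
oracle_cosine <- function(x, y) {
  num <- 0; dx <- 0; dy <- 0
  for (t in seq_along(x)) {
    num <- num + x[t] * y[t]
    dx <- dx + x[t]^2
    dy <- dy + y[t]^2
  }
  num / (sqrt(dx) * sqrt(dy))
}

# unconstrained trilinear ALS on an explicit Khatri-Rao design; only suitable
# for small noiseless tensors
oracle_parafac <- function(X, F, maxit = 500, seed = 42, tol = 1e-14) {
  set.seed(seed)
  d <- dim(X)
  kr <- function(P, Q) {
    out <- matrix(0, nrow(P) * nrow(Q), ncol(P))
    for (f in seq_len(ncol(P))) out[, f] <- as.vector(outer(Q[, f], P[, f]))
    out
  }
  B <- matrix(abs(rnorm(d[2] * F)), d[2], F)
  C <- matrix(abs(rnorm(d[3] * F)), d[3], F)
  X1 <- matrix(X, d[1])
  X2 <- matrix(aperm(X, c(2, 1, 3)), d[2])
  X3 <- matrix(aperm(X, c(3, 1, 2)), d[3])
  sse_prev <- Inf
  for (it in seq_len(maxit)) {
    A <- t(qr.solve(kr(C, B), t(X1)))
    B <- t(qr.solve(kr(C, A), t(X2)))
    C <- t(qr.solve(kr(B, A), t(X3)))
    sse <- sum((X1 - A %*% t(kr(C, B)))^2)
    if (is.finite(sse_prev) && abs(sse_prev - sse) <= tol * max(sse_prev, 1e-300))
      break
    sse_prev <- sse
  }
  list(A = A, B = B, C = C, sse = sse, iterations = it)
}

# greedy one-to-one pairing of oracle components to reference loadings by
# absolute emission congruence (adequate for well-separated fixtures)
oracle_match <- function(B_fit, B_ref) {
  F <- ncol(B_ref)
  taken <- integer(0)
  out <- integer(F)
  for (f in seq_len(F)) {
    sims <- vapply(seq_len(ncol(B_fit)), function(g)
      abs(oracle_cosine(B_fit[, g], B_ref[, f])), numeric(1))
    sims[taken] <- -Inf
    out[f] <- which.max(sims)
    taken <- c(taken, out[f])
  }
  out
}
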