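# Independent finite-state CME oracle: enumerate all states on a bounded
# lattice, build the generator explicitly from microscopic propensities, and
# compute exact moments by matrix exponentiation. Used to validate the
# moment-approximation methods; entirely independent of the ODE machinery.

cme_oracle <- function(net, n0, t_grid, nmax, theta = NULL) {
  M <- net$M
  states <- as.matrix(expand.grid(lapply(nmax, function(m) 0:m)))
  S <- nrow(states)
  key <- function(n) sum(n * cumprod(c(1, nmax[-M] + 1))) + 1
  nu <- stoichiometry_matrices(net)$nu
  Q <- matrix(0, S, S)
  for (s in seq_len(S)) {
    n <- states[s, ]
    a <- microscopic_propensity(net, n, 0, theta)
    for (r in seq_len(net$R)) {
      if (a[r] <= 0) next
      n2 <- n + nu[, r]
      if (any(n2 < 0) || any(n2 > nmax)) next
      Q[key(n2), s] <- Q[key(n2), s] + a[r]
      Q[s, s] <- Q[s, s] - a[r]
    }
  }
  p0 <- numeric(S)
  p0[key(n0)] <- 1
  omega_i <- net$compiled$omega_i
  x <- states / rep(omega_i, each = S)
  res <- lapply(t_grid, function(t) {
    p <- as.numeric(Matrix::expm(Matrix::Matrix(Q * t)) %*% p0)
    mu <- colSums(p * x)
    Sig <- t(x) %*% (p * x) - mu %o% mu
    list(mu = mu, Sig = Sig)
  })
  list(mu = t(sapply(res, `[[`, "mu")),
       Sig = lapply(res, `[[`, "Sig"))
}
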