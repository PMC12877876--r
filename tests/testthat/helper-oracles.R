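# Independent reference implementations used as oracles. Everything here is
# written directly from the model formulas in plain base R, without calling
# the package's own branch-statistic or likelihood code.

# Poisson mean of hidden generations over the window [te, ts] (backward time)
ref_lambda <- function(ts, te, q, rho) {
  num <- (1 - rho - q) * exp(-(1 - q) * te) + rho
  den <- (1 - rho - q) * exp(-(1 - q) * ts) + rho
  pmax(2 * q * (ts - te) + 2 * (log(num) - log(den)), 0)
}

# joint probability of bridging the window with i hidden generations,
# evaluated in log space so large i and large windows do not overflow
ref_p1 <- function(i, ts, te, q, rho) {
  lam <- ref_lambda(ts, te, q, rho)
  ilog <- i * log(lam)  # NaN at 0 * log(0), fixed up next
  ilog[i == 0] <- 0
  exp(-(1 + q) * (ts - te) + ilog - lgamma(i + 1))
}

# mutations given generations, with the founding division included
ref_pm <- function(m, i, mu) {
  exp(-(i + 1) * mu) * ((i + 1) * mu)^m / factorial(m)
}

# pendant message P(nu | tau_s) tabulated on grid nodes (linear space)
ref_pendant <- function(m, tnodes, q, mu, rho, imax) {
  i <- 0:imax
  vapply(tnodes, function(ts) {
    rho * sum(ref_pm(m, i, mu) * ref_p1(i, ts, 0, q, rho))
  }, numeric(1))
}

# internal message by explicit trapezoid over end times on grid nodes <= ts
ref_internal <- function(m, A, B, tnodes, q, mu, rho, imax) {
  G1 <- length(tnodes)
  dt <- tnodes[2] - tnodes[1]
  i <- 0:imax
  pmv <- ref_pm(m, i, mu)
  out <- numeric(G1)
  for (g in seq(2, G1)) {
    hs <- 1:g
    w <- rep(1, g)
    w[c(1, g)] <- 0.5
    integ <- vapply(i, function(ii) {
      sum(w * ref_p1(ii, tnodes[g], tnodes[hs], q, rho) *
            2 * A[hs] * B[hs]) * dt
    }, numeric(1))
    out[g] <- sum(pmv * integ)
  }
  out
}

# root likelihood: trapezoid of 2 A B over the whole grid
ref_root <- function(A, B, tnodes) {
  G1 <- length(tnodes)
  dt <- tnodes[2] - tnodes[1]
  w <- rep(1, G1)
  w[c(1, G1)] <- 0.5
  sum(w * 2 * A * B) * dt
}

# brute-force likelihood of the 3-leaf tree ((A:m1,B:m2):m12,C:m3); on the
# same grid and quadrature rule the DP must agree to round-off
ref_loglik_3leaf <- function(m1, m2, m12, m3, tnodes, q, mu, rho, imax) {
  A <- ref_pendant(m1, tnodes, q, mu, rho, imax)
  B <- ref_pendant(m2, tnodes, q, mu, rho, imax)
  C <- ref_pendant(m3, tnodes, q, mu, rho, imax)
  AB <- ref_internal(m12, A, B, tnodes, q, mu, rho, imax)
  log(ref_root(AB, C, tnodes))
}

# caterpillar 4-leaf tree (((A:m1,B:m2):m12,C:m3):m123,D:m4)
ref_loglik_4leaf <- function(m1, m2, m12, m3, m123, m4, tnodes, q, mu, rho,
                             imax) {
  A <- ref_pendant(m1, tnodes, q, mu, rho, imax)
  B <- ref_pendant(m2, tnodes, q, mu, rho, imax)
  C <- ref_pendant(m3, tnodes, q, mu, rho, imax)
  D <- ref_pendant(m4, tnodes, q, mu, rho, imax)
  AB <- ref_internal(m12, A, B, tnodes, q, mu, rho, imax)
  ABC <- ref_internal(m123, AB, C, tnodes, q, mu, rho, imax)
  log(ref_root(ABC, D, tnodes))
}

# build a mutation tree from a Newick string
nwk <- function(s) as_mutation_tree(ape::read.tree(text = s))
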