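# Independent oracles used across the suite; none of these call the
# package's own closed forms for the quantity they check.

# decay ratio x: plain bisection on (1 - x)^2 - x/(K*mu) over (0, 1)
bisect_x <- function(K, mu) {
  g <- function(x) (1 - x)^2 - x / (K * mu)
  lo <- 0
  hi <- 1 - 1e-15
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# dimer diffusive equilibrium by root finding on the balance conditions
rootfind_dimer_eq <- function(phi, K) {
  g <- function(P1) {
    P0 <- 1 - phi - P1 / 2
    P2 <- (phi - P1 / 2) / (1 + K)
    4 * P0 * P2 - P1^2
  }
  P1 <- stats::uniroot(g, c(1e-14, 2 * phi), tol = 1e-15)$root
  P2 <- (phi - P1 / 2) / (1 + K)
  c(P0 = 1 - phi - P1 / 2, P1 = P1, P2 = P2, PD = K * P2)
}

# stationary distribution of a continuous-time Markov chain by linear algebra
ctmc_stationary <- function(Q) {
  n <- nrow(Q)
  qr.solve(rbind(t(Q), rep(1, n)), c(rep(0, n), 1))
}

std_err <- function(x) stats::sd(x) / sqrt(length(x))
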