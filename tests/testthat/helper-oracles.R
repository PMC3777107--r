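# Independent numerical oracles: every closed-form marginal is checked
# against adaptive 1-D quadrature of the defining integral (the oracle
# never calls the package's closed forms).

# marginal ratio m(z; m0) / prod(phi(z_i)) for one group by quadrature
groupMarginalQuad <- function(z, m0, s2 = 0.5) {
  if (length(z) == 0L) return(1)
  num <- stats::integrate(function(mu)
    vapply(mu, function(m) prod(stats::dnorm(z, m, 1)), numeric(1)) *
      stats::dnorm(mu, m0, sqrt(s2)),
    -10, 10, rel.tol = 1e-12, abs.tol = 0, subdivisions = 500L)$value
  num / prod(stats::dnorm(z))
}

# SEM BF by quadrature under the 50:50 mixture prior
semBFQuad <- function(z, mu0 = 1.5, s2 = 0.5) {
  0.5 * groupMarginalQuad(z, +mu0, s2) +
    0.5 * groupMarginalQuad(z, -mu0, s2)
}

# single-grouping GEM BF: product of independent per-group quadratures
gemBFQuad <- function(zPlus, zMinus, mu0 = 1.5, s2 = 0.5) {
  groupMarginalQuad(zPlus, +mu0, s2) * groupMarginalQuad(zMinus, -mu0, s2)
}

# GEM-NMD BF by brute-force enumeration over a scheme's groupings,
# quadrature per group (carriers listed per variant)
gemNmdBFQuad <- function(carrierList, y, scheme, mu0 = 1.5, s2 = 0.5) {
  asg <- groupingAssignments(scheme)
  w <- groupingWeights(scheme)
  total <- 0
  for (g in seq_len(nrow(asg))) {
    zp <- y[unlist(carrierList[asg[g, ]], use.names = FALSE)]
    zm <- y[unlist(carrierList[!asg[g, ]], use.names = FALSE)]
    total <- total + w[g] * gemBFQuad(zp, zm, mu0, s2)
  }
  total
}

# posterior mean of mu by Riemann-grid quadrature (1e5 points)
semPosteriorMeanGrid <- function(z, mu0 = 1.5, s2 = 0.5, nGrid = 1e5) {
  mu <- seq(-10, 10, length.out = nGrid)
  prior <- 0.5 * stats::dnorm(mu, mu0, sqrt(s2)) +
    0.5 * stats::dnorm(mu, -mu0, sqrt(s2))
  loglik <- vapply(mu, function(m) sum(stats::dnorm(z, m, 1, log = TRUE)),
                   numeric(1))
  wts <- prior * exp(loglik - max(loglik))
  sum(mu * wts) / sum(wts)
}

# random small carrier vector: mixture of null and shifted draws
randomCarriers <- function(n = sample(1:10, 1)) {
  shift <- sample(c(-2, 0, 1, 2), 1)
  stats::rnorm(n, shift, 1)
}

relErr <- function(a, b) abs(a - b) / pmax(abs(b), .Machine$double.eps)
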