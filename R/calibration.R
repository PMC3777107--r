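## Frequentist calibration of the Bayes factors.
##
## Under the null the carriers' trait values are i.i.d. standard normal, so
## sqrt(n) * mean(z) is standard normal and the SEM BF — a strictly
## increasing function of |mean(z)| for fixed n — has a null distribution
## that can be evaluated analytically. GEM-NMD mixes groupings with
## different signs, so its critical values come from Monte-Carlo
## simulation.

#' Analytic critical value of the SEM Bayes factor
#'
#' The BF threshold whose exceedance probability under the null equals the
#' type I error rate alpha, for a gene with n PTV carriers. Because the SEM
#' BF is strictly increasing in |mean(z)| and \eqn{\sqrt{n}\,\bar z} is
#' standard normal under the null, the critical value is simply the BF
#' evaluated at carrier mean \eqn{\Phi^{-1}(1-\alpha/2)/\sqrt{n}} (exact,
#' two-sided).
#'
#' @param alpha type I error rate, in (0, 1).
#' @param n number of PTV carriers (>= 1).
#' @param hyper a \code{\link{ModelHyperparameters}}.
#' @return The critical Bayes factor (linear scale).
#' @examples
#' semCriticalValue(0.01, 3)  # 8.77 with the default prior
#' @export
semCriticalValue <- function(alpha, n, hyper = modelHyper()) {
  stopifnot(alpha > 0, alpha < 1, n >= 1)
  zbar <- stats::qnorm(1 - alpha / 2) / sqrt(n)
  exp(semLogBFStats(as.integer(n), n * zbar, hyper))
}

#' P-value of an observed SEM Bayes factor
#'
#' The probability, under the null, of a BF at least as large as the one
#' observed, for fixed carrier count n. The BF is inverted to the carrier
#' mean m* by monotone bisection and the p-value is the two-sided normal
#' tail \eqn{2(1 - \Phi(\sqrt{n}\,m^*))}. When the BF was computed from
#' data, this equals the Collapse p-value on the same data.
#'
#' @param bfValue observed Bayes factor (linear scale).
#' @param n number of PTV carriers.
#' @param hyper a \code{\link{ModelHyperparameters}}.
#' @return two-sided p-value; 1 when \code{bfValue} is at or below the
#'   minimum attainable BF (carrier mean 0).
#' @examples
#' semPvalueFromBF(semCriticalValue(0.01, 3), 3)  # 0.01
#' @export
semPvalueFromBF <- function(bfValue, n, hyper = modelHyper()) {
  stopifnot(bfValue > 0, n >= 1)
  target <- log(bfValue)
  f <- function(m) semLogBFStats(as.integer(n), n * m, hyper) - target
  if (f(0) >= 0) return(1)
  hi <- 20
  if (f(hi) < 0)
    stop("Bayes factor too large to invert within the bisection bracket")
  lo <- 0
  # bisection to 1e-12 relative on the carrier mean
  while ((hi - lo) > 1e-12 * max(1, hi)) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  mstar <- (lo + hi) / 2
  2 * stats::pnorm(-sqrt(n) * mstar)
}

#' Monte-Carlo critical value of the GEM-NMD Bayes factor
#'
#' Simulates null genes (carrier trait values i.i.d. standard normal),
#' computes the GEM-NMD BF for each replicate, and returns the empirical
#' (1 - alpha) quantile (order statistic at \code{ceiling((1-alpha) * R)})
#' with a bootstrap 95% confidence interval. The simulated gene has
#' \code{n} variants, each carried by a single individual, of which
#' \code{nEscape} (default 1) escape NMD; an explicit
#' \code{\link{GroupingScheme}} overrides the default NMD-informed scheme.
#'
#' The bootstrap CI uses the order-statistics representation of the
#' empirical-quantile bootstrap: the bootstrap replicate of the quantile is
#' the original order statistic at a Binomial(R, 1-alpha) rank, so ranks
#' are drawn directly instead of resampling R values per replicate.
#'
#' @param alpha type I error rate.
#' @param n number of PTV carriers (= variants; each seen in one carrier).
#' @param hyper a \code{\link{ModelHyperparameters}}.
#' @param scheme optional \code{\link{GroupingScheme}}; default is the
#'   NMD-informed scheme for a gene with \code{nEscape} escaping variants.
#' @param nEscape number of NMD-escaping variants in the simulated gene.
#' @param replicates number of null replicates (default 1e6; must satisfy
#'   replicates * alpha >= 50).
#' @param seed integer seed (mandatory, recorded in the output).
#' @param bootstrap number of bootstrap draws for the CI.
#' @return list with \code{critical_bf}, \code{ci} (length-2), \code{alpha},
#'   \code{n}, \code{replicates}, \code{seed}.
#' @examples
#' gemCriticalValueMC(0.01, 3, replicates = 1e4, seed = 7)
#' @export
gemCriticalValueMC <- function(alpha, n, hyper = modelHyper(),
                               scheme = NULL, nEscape = 1L,
                               replicates = 1e6, seed,
                               bootstrap = 2000L) {
  stopifnot(alpha > 0, alpha < 1, n >= 1)
  if (missing(seed)) stop("'seed' is required for reproducible calibration")
  replicates <- as.integer(replicates)
  if (replicates * alpha < 50)
    stop("replicates * alpha = ", replicates * alpha,
         " < 50: increase 'replicates' for a stable tail quantile")
  if (is.null(scheme)) {
    stopifnot(nEscape >= 0, nEscape <= n)
    trig <- rep(TRUE, n); if (nEscape > 0) trig[seq_len(nEscape)] <- FALSE
    scheme <- enumerateGroupings(n, "nmd_default", nmdTrigger = trig)
  }
  asg <- scheme@assignments; w <- scheme@weights
  if (!length(w)) stop("the grouping scheme must carry weights")
  lbf <- withSeed(seed, {
    # one variant per carrier: grouping sums are linear maps of z
    Z <- matrix(stats::rnorm(replicates * n), nrow = replicates)
    acc <- matrix(-Inf, nrow = replicates, ncol = nrow(asg))
    for (g in seq_len(nrow(asg))) {
      a <- asg[g, ]
      Sp <- if (any(a)) Z[, a, drop = FALSE] %*% rep(1, sum(a)) else
        numeric(replicates)
      Sm <- if (any(!a)) Z[, !a, drop = FALSE] %*% rep(1, sum(!a)) else
        numeric(replicates)
      acc[, g] <- log(w[g]) +
        logMarginalRatioVec(sum(a), as.numeric(Sp), +hyper@mu0,
                            hyper@sigma0Sq) +
        logMarginalRatioVec(sum(!a), as.numeric(Sm), -hyper@mu0,
                            hyper@sigma0Sq)
    }
    m <- apply(acc, 1L, max)
    m + log(rowSums(exp(acc - m)))
  })
  srt <- sort(lbf)
  rank0 <- ceiling((1 - alpha) * replicates)
  crit <- exp(srt[rank0])
  ci <- withSeed(seed + 1L, {
    ranks <- stats::qbinom(stats::runif(bootstrap), replicates, 1 - alpha)
    ranks <- pmin(pmax(ranks, 1L), replicates)
    exp(stats::quantile(srt[ranks], c(0.025, 0.975), names = FALSE))
  })
  list(critical_bf = crit, ci = ci, alpha = alpha, n = n,
       replicates = replicates, seed = seed)
}

#' Minimum PTV carriers for a target power
#'
#' Smallest carrier count n such that the two-sided level-alpha test of a
#' carrier mean shift beta (SD units) on the standardized trait scale has
#' at least the target power:
#' \deqn{\Phi(\sqrt{n}|\beta| - z_{1-\alpha/2}) +
#'       \Phi(-\sqrt{n}|\beta| - z_{1-\alpha/2}) \ge \mathrm{power}.}
#' By default alpha is the exome-wide Bonferroni level 0.05 / nGenes.
#'
#' @param effect carrier mean shift beta in SD units (nonzero).
#' @param alpha significance level; default \code{0.05 / nGenes}.
#' @param targetPower required power, in (0, 1); default 0.8.
#' @param nGenes Bonferroni denominator for the default alpha.
#' @return smallest sufficient carrier count (integer).
#' @examples
#' minCarriersForPower(2)    # 8
#' minCarriersForPower(1.5)  # 14
#' minCarriersForPower(1)    # 31
#' @export
minCarriersForPower <- function(effect, alpha = 0.05 / nGenes,
                                targetPower = 0.8, nGenes = 20000) {
  stopifnot(effect != 0, targetPower > 0, targetPower < 1,
            alpha > 0, alpha < 1)
  b <- abs(effect)
  zc <- stats::qnorm(1 - alpha / 2)
  pow <- function(n) stats::pnorm(sqrt(n) * b - zc) +
    stats::pnorm(-sqrt(n) * b - zc)
  n <- 1L
  while (pow(n) < targetPower) {
    n <- n + 1L
    if (n > 1e6L)
      stop("target power unreachable within 1e6 carriers for effect ",
           effect)
  }
  n
}

#' Cohort size needed to observe enough PTV carriers
#'
#' If a fraction f of the population carries a PTV at the gene, the number
#' of carriers among N sampled individuals is Binomial(N, f). Returns the
#' smallest N such that at least \code{nTarget} carriers are observed with
#' probability \code{prob}, by exact binomial tail evaluation.
#'
#' @param nTarget required carrier count.
#' @param f population carrier fraction, in (0, 1).
#' @param prob required probability of success (default 0.8).
#' @return smallest sufficient cohort size N.
#' @examples
#' cohortSizeForCarriers(8, 0.001)
#' @export
cohortSizeForCarriers <- function(nTarget, f, prob = 0.8) {
  stopifnot(nTarget >= 1, f > 0, f < 1, prob > 0, prob < 1)
  tail <- function(N) stats::pbinom(nTarget - 1, N, f, lower.tail = FALSE)
  lo <- nTarget
  hi <- max(nTarget, ceiling(nTarget / f))
  while (tail(hi) < prob) hi <- hi * 2L
  while (lo < hi) {  # tail(N) is nondecreasing in N
    mid <- (lo + hi) %/% 2
    if (tail(mid) >= prob) hi <- mid else lo <- mid + 1
  }
  lo
}

#' SEM Bayes factor along a fixed p-value contour
#'
#' For a fixed two-sided p-value, the carrier mean that attains it is
#' \eqn{\Phi^{-1}(1-p/2)/\sqrt{n}}; the SEM BF at that mean shows how the
#' Bayesian evidence varies with carrier count at constant frequentist
#' significance. The curve rises and then falls with n: very small n
#' requires implausibly extreme means (downweighted by the prior), while
#' large n corresponds to small shifts that the alternative also finds
#' unlikely — the Bayes-factor side of Lindley's paradox.
#'
#' @param p fixed two-sided p-value, in (0, 1).
#' @param n carrier count (vectorized).
#' @param hyper a \code{\link{ModelHyperparameters}}.
#' @return data.frame with columns \code{n}, \code{mean_value} (the carrier
#'   mean attaining p) and \code{bf}.
#' @examples
#' bfAtFixedPvalue(0.001, c(1, 3, 50))
#' @export
bfAtFixedPvalue <- function(p, n, hyper = modelHyper()) {
  stopifnot(p > 0, p < 1, all(n >= 1))
  zbar <- stats::qnorm(1 - p / 2) / sqrt(n)
  lbf <- vapply(seq_along(n), function(i)
    semLogBFStats(as.integer(n[i]), n[i] * zbar[i], hyper), numeric(1))
  data.frame(n = n, mean_value = zbar, bf = exp(lbf))
}

#' Critical-value table for the Bayes factors
#'
#' Convenience wrapper assembling a calibration table over a grid of type I
#' error rates and carrier counts: analytic critical values for the SEM,
#' Monte-Carlo for GEM-NMD.
#'
#' @param alphas type I error rates.
#' @param ns PTV carrier counts.
#' @param models subset of \code{c("SEM", "GEM-NMD")}.
#' @param hyper a \code{\link{ModelHyperparameters}}.
#' @param replicates Monte-Carlo replicates for GEM-NMD rows.
#' @param seed integer seed for the Monte-Carlo rows.
#' @param nEscape NMD-escaping variants in the simulated GEM-NMD gene.
#' @return data.frame with columns model, alpha, nptv, critical_bf, ci_low,
#'   ci_high, method, replicates, seed.
#' @examples
#' calibrationTable(alphas = 0.01, ns = 3:5, models = "SEM")
#' @export
calibrationTable <- function(alphas = c(0.01, 0.001, 1e-4, 1e-5),
                             ns = 3:5, models = c("SEM", "GEM-NMD"),
                             hyper = modelHyper(), replicates = 1e6,
                             seed = 1L, nEscape = 1L) {
  models <- match.arg(models, several.ok = TRUE)
  rows <- list()
  for (model in models) for (a in alphas) for (n in ns) {
    if (model == "SEM") {
      rows[[length(rows) + 1L]] <- data.frame(
        model = "SEM", alpha = a, nptv = n,
        critical_bf = semCriticalValue(a, n, hyper),
        ci_low = NA_real_, ci_high = NA_real_, method = "analytic",
        replicates = NA_integer_, seed = NA_integer_)
    } else {
      mc <- gemCriticalValueMC(a, n, hyper, nEscape = nEscape,
                               replicates = replicates,
                               seed = seed + 1000L * n)
      rows[[length(rows) + 1L]] <- data.frame(
        model = "GEM-NMD", alpha = a, nptv = n,
        critical_bf = mc$critical_bf,
        ci_low = mc$ci[1], ci_high = mc$ci[2], method = "monte_carlo",
        replicates = mc$replicates, seed = mc$seed)
    }
  }
  do.call(rbind, rows)
}
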