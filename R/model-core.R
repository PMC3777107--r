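## Closed-form Bayes factors for PTV carrier mean shifts.
##
## All marginal likelihoods reduce to conjugate normal-normal integrals over
## the carrier values z: with z_i | mu ~ N(mu, 1) i.i.d. and mu ~ N(m0, v),
## the ratio of the marginal of z to the null density prod phi(z_i; 0, 1) is
##
##   log m(z; m0) / prod phi(z_i)
##     = -0.5*log(1 + n*v) + (S + m0/v)^2 / (2*(n + 1/v)) - m0^2 / (2*v)
##
## with S = sum(z). It depends on the data only through (n, S); everything
## below is built from this kernel in natural-log space.

# log of [marginal of n carriers under mu ~ N(m0, v)] / [null density]
logMarginalRatio <- function(n, S, m0, v) {
  if (n == 0L) return(0)
  -0.5 * log1p(n * v) + (S + m0 / v)^2 / (2 * (n + 1 / v)) - m0^2 / (2 * v)
}

# vectorized over S (used by the Monte-Carlo calibration)
logMarginalRatioVec <- function(n, S, m0, v) {
  if (n == 0L) return(rep(0, length(S)))
  -0.5 * log1p(n * v) + (S + m0 / v)^2 / (2 * (n + 1 / v)) - m0^2 / (2 * v)
}

# SEM log BF from sufficient statistics; vectorized over S
semLogBFStats <- function(n, S, hyper = modelHyper()) {
  mu0 <- hyper@mu0; v <- hyper@sigma0Sq
  lp <- logMarginalRatioVec(n, S, +mu0, v)
  lm <- logMarginalRatioVec(n, S, -mu0, v)
  m <- pmax(lp, lm)
  m + log(0.5 * exp(lp - m) + 0.5 * exp(lm - m))
}

#' Similar-effects model Bayes factor
#'
#' Bayes factor comparing the similar-effects model (SEM), in which every
#' PTV carrier's trait value is shifted by a common mean \eqn{\mu}, against
#' the null model in which all trait values are standard normal. The prior
#' on \eqn{\mu} is the symmetric 50:50 mixture
#' \eqn{0.5\,N(\mu_0,\sigma_0^2) + 0.5\,N(-\mu_0,\sigma_0^2)}, reflecting
#' that the direction of a truncating variant's effect is unknown a priori.
#'
#' Because non-carriers have the same distribution under both models, the
#' BF involves only the carriers' trait values, and reduces to a function
#' of the carrier count n and the carrier mean; computation is in log space
#' via log-sum-exp.
#'
#' @param carriers numeric vector of carrier trait values (on the
#'   standardized scale) or a \code{\link{CarrierTraits}} object.
#' @param hyper a \code{\link{ModelHyperparameters}} object.
#' @return A \code{\link{BFResult}} with the natural-log Bayes factor.
#'   With zero carriers the BF is 1 (no evidence) and a warning is issued.
#' @examples
#' semLogBF(c(1.8, 2.2, 1.5))
#' bf(semLogBF(c(1.8, 2.2, 1.5)))
#' @rdname semLogBF
#' @export
setMethod("semLogBF", "numeric", function(carriers, hyper = modelHyper()) {
  if (any(!is.finite(carriers))) stop("carrier trait values must be finite")
  n <- length(carriers)
  if (n == 0L) {
    warning("no PTV carriers: BF = 1 (no evidence)")
    return(bfResult(0))
  }
  bfResult(semLogBFStats(n, sum(carriers), hyper),
           posterior = semPosteriorStats(n, sum(carriers), hyper))
})

#' @rdname semLogBF
setMethod("semLogBF", "CarrierTraits", function(carriers,
                                                hyper = modelHyper()) {
  semLogBF(carriers@z, hyper)
})

# exact two-component conjugate posterior for mu given (n, S)
semPosteriorStats <- function(n, S, hyper = modelHyper()) {
  mu0 <- hyper@mu0; v <- hyper@sigma0Sq
  A <- n + 1 / v
  lw <- c(logMarginalRatio(n, S, +mu0, v), logMarginalRatio(n, S, -mu0, v))
  w <- exp(lw - logSumExp(lw))
  effectPosterior(weights = w,
                  means = c((S + mu0 / v) / A, (S - mu0 / v) / A),
                  sds = rep(sqrt(1 / A), 2L))
}

#' Posterior distribution of the SEM carrier mean shift
#'
#' Exact conjugate posterior of the common carrier mean shift \eqn{\mu}
#' under the SEM: a two-component mixture of normals, component
#' \eqn{j \in \{+,-\}} having variance \eqn{(n + 1/\sigma_0^2)^{-1}}, mean
#' \eqn{(n\bar z \pm \mu_0/\sigma_0^2)(n + 1/\sigma_0^2)^{-1}} and weight
#' proportional to the corresponding marginal likelihood component.
#'
#' @inheritParams semLogBF
#' @return An \code{\link{EffectPosterior}}. With zero carriers the prior
#'   itself is returned.
#' @examples
#' post <- semPosteriorMu(c(-1.1, -1.4, -0.9, -1.3, -1.2))
#' posteriorMean(post)
#' credibleInterval(post)
#' @rdname semPosteriorMu
#' @export
setMethod("semPosteriorMu", "numeric", function(carriers,
                                                hyper = modelHyper()) {
  if (any(!is.finite(carriers))) stop("carrier trait values must be finite")
  n <- length(carriers)
  if (n == 0L)
    return(effectPosterior(c(0.5, 0.5), c(hyper@mu0, -hyper@mu0),
                           rep(sqrt(hyper@sigma0Sq), 2L)))
  semPosteriorStats(n, sum(carriers), hyper)
})

#' @rdname semPosteriorMu
setMethod("semPosteriorMu", "CarrierTraits",
          function(carriers, hyper = modelHyper())
            semPosteriorMu(carriers@z, hyper))

#' Bayes factor for one grouping of the grouped-effects model
#'
#' Single-grouping GEM Bayes factor: variants (hence their carriers) are
#' split into a "+" and a "-" group with independent mean shifts
#' \eqn{\mu_+ \sim N(+\mu_0, \sigma_0^2)} and
#' \eqn{\mu_- \sim N(-\mu_0, \sigma_0^2)}, so the BF factorizes over the
#' two groups; an empty group contributes a factor of 1.
#'
#' @param zPlus numeric trait values of carriers in the "+" group (may be
#'   empty).
#' @param zMinus numeric trait values of carriers in the "-" group (may be
#'   empty).
#' @param hyper a \code{\link{ModelHyperparameters}} object.
#' @return A \code{\link{BFResult}}.
#' @examples
#' gemLogBFSingle(c(1.2, 0.8), c(-1.5))
#' @export
gemLogBFSingle <- function(zPlus, zMinus, hyper = modelHyper()) {
  if (any(!is.finite(c(zPlus, zMinus))))
    stop("carrier trait values must be finite")
  lbf <- logMarginalRatio(length(zPlus), sum(zPlus), +hyper@mu0,
                          hyper@sigma0Sq) +
         logMarginalRatio(length(zMinus), sum(zMinus), -hyper@mu0,
                          hyper@sigma0Sq)
  bfResult(lbf)
}

#' Enumerate groupings of k variants into two effect groups
#'
#' Builds a \code{\link{GroupingScheme}} over assignments of the k variants
#' of a gene to the "+" and "-" groups.
#'
#' Modes:
#' \describe{
#'   \item{\code{full}}{all \eqn{2^k} assignments (capped at k <= 20);
#'     weights left unset.}
#'   \item{\code{all_same}}{the two assignments placing every variant in
#'     one group; weight 0.5 each, which recovers the SEM.}
#'   \item{\code{nmd_default}}{up to four distinct assignments — all "+",
#'     all "-", NMD-triggers "+" / escapers "-", and its mirror — with
#'     weight 1/4 each. When the NMD partition is degenerate (no escapers
#'     or no triggers) duplicate assignments are merged and their weights
#'     summed, reducing exactly to the SEM scheme.}
#' }
#'
#' @param k number of variants (k >= 1).
#' @param mode one of \code{"full"}, \code{"nmd_default"}, \code{"all_same"}.
#' @param nmdTrigger logical vector of length k, TRUE where the variant is
#'   predicted to trigger NMD; required for \code{nmd_default}.
#' @return A \code{\link{GroupingScheme}}.
#' @examples
#' enumerateGroupings(3, "full")
#' enumerateGroupings(2, "nmd_default", nmdTrigger = c(TRUE, FALSE))
#' @export
enumerateGroupings <- function(k,
                               mode = c("nmd_default", "full", "all_same"),
                               nmdTrigger = NULL) {
  mode <- match.arg(mode)
  stopifnot(k >= 1L)
  if (mode == "full") {
    if (k > 20L)
      stop("full enumeration is capped at k <= 20 (2^k groupings); ",
           "use a sparse scheme for larger genes")
    asg <- as.matrix(expand.grid(rep(list(c(TRUE, FALSE)), k),
                                 KEEP.OUT.ATTRS = FALSE))
    dimnames(asg) <- NULL
    return(groupingScheme(asg))
  }
  if (mode == "all_same") {
    asg <- rbind(rep(TRUE, k), rep(FALSE, k))
    return(groupingScheme(asg, weights = c(0.5, 0.5)))
  }
  # nmd_default
  if (is.null(nmdTrigger) || length(nmdTrigger) != k ||
      any(is.na(nmdTrigger)))
    stop("'nmdTrigger' (logical, length k, no NA) is required for the ",
         "NMD-informed default scheme")
  asg <- rbind(rep(TRUE, k), rep(FALSE, k), nmdTrigger, !nmdTrigger)
  dimnames(asg) <- NULL
  w <- rep(0.25, 4L)
  key <- apply(asg, 1L, paste, collapse = "")
  keep <- !duplicated(key)
  wMerged <- as.numeric(tapply(w, key, sum)[key[keep]])
  groupingScheme(asg[keep, , drop = FALSE], weights = wMerged)
}

#' NMD-informed grouped-effects model Bayes factor
#'
#' GEM-NMD Bayes factor for one gene: a weighted mixture
#' \eqn{BF = \sum_g w_g BF_g} over groupings g of the gene's variants into
#' two opposite-effect groups. The default scheme places weight 1/4 on each
#' of the four NMD-informed assignments (all "+", all "-", triggers-vs-
#' escapers and its mirror), merging duplicates when the NMD partition is
#' degenerate — with no escaping variant the model reduces exactly to the
#' SEM. The result carries the per-grouping decomposition, the posterior
#' grouping weights (proportional to \eqn{w_g BF_g}) and model-averaged
#' per-variant effect posteriors.
#'
#' @param gene a \code{\link{GeneCarrierSet}}.
#' @param cohort a \code{\link{CohortTraits}} (standardized trait values),
#'   or a numeric vector of trait values indexed by the gene's carrier
#'   indices.
#' @param hyper a \code{\link{ModelHyperparameters}}.
#' @param scheme a \code{\link{GroupingScheme}} with weights summing to 1,
#'   or NULL for the NMD-informed default built from the gene's flags.
#' @return A \code{\link{BFResult}}; \code{perGrouping(x)} holds the
#'   decomposition and \code{effectPosteriors(x)} a per-variant list of
#'   \code{\link{EffectPosterior}} objects.
#' @examples
#' gene <- geneCarrierSet("G", c("v1", "v2"), list(1L, 2L),
#'                        nmd = c("trigger", "escape"))
#' coh <- cohortTraits(c(1.8, -1.6, 0.2, -0.1))
#' res <- gemNmdLogBF(gene, coh)
#' perGrouping(res)
#' @rdname gemNmdLogBF
#' @export
setMethod("gemNmdLogBF", signature(gene = "GeneCarrierSet"),
  function(gene, cohort, hyper = modelHyper(), scheme = NULL) {
    y <- if (is(cohort, "CohortTraits")) cohort@values else as.numeric(cohort)
    k <- nVariants(gene)
    if (is.null(scheme)) {
      flags <- gene@nmd
      if (any(is.na(flags)))
        stop("every variant needs an NMD flag for the default GEM-NMD ",
             "scheme; classify with classifyNmd() or supply 'scheme'")
      scheme <- enumerateGroupings(k, "nmd_default",
                                   nmdTrigger = flags == "trigger")
    }
    asg <- scheme@assignments
    w <- scheme@weights
    if (!length(w))
      stop("the grouping scheme must carry weights summing to 1")
    if (ncol(asg) != k)
      stop("scheme covers ", ncol(asg), " variants but the gene has ", k)
    if (nrow(asg) > 2^20)
      stop("dense schemes beyond 2^20 groupings are not supported; ",
           "supply a sparse scheme")
    G <- nrow(asg)
    lbf <- numeric(G)
    for (g in seq_len(G)) {
      plusIdx <- unlist(gene@carriers[asg[g, ]], use.names = FALSE)
      minusIdx <- unlist(gene@carriers[!asg[g, ]], use.names = FALSE)
      lbf[g] <- logBF(gemLogBFSingle(y[plusIdx], y[minusIdx], hyper))
    }
    total <- logSumExp(lbf, w)
    lpost <- log(w) + lbf - total
    pg <- data.frame(
      grouping = apply(asg, 1L, function(a)
        paste0(ifelse(a, "+", "-"), collapse = "")),
      weight = w, log_bf = lbf, post_weight = exp(lpost))
    bfResult(total, perGrouping = pg,
             posterior = gemVariantPosteriors(gene, y, hyper, asg,
                                              exp(lpost)))
  })

# model-averaged per-variant effect posterior: under each grouping the
# variant inherits its group's conjugate posterior; mix across groupings
# with the posterior grouping weights.
gemVariantPosteriors <- function(gene, y, hyper, asg, postW) {
  v <- hyper@sigma0Sq; mu0 <- hyper@mu0
  k <- ncol(asg); G <- nrow(asg)
  groupPost <- function(idx, sign) {
    n <- length(idx); S <- sum(y[idx])
    A <- n + 1 / v
    c(mean = (S + sign * mu0 / v) / A, sd = sqrt(1 / A))
  }
  out <- vector("list", k)
  for (j in seq_len(k)) {
    mns <- sds <- numeric(G)
    for (g in seq_len(G)) {
      inPlus <- asg[g, j]
      idx <- unlist(gene@carriers[asg[g, ] == inPlus], use.names = FALSE)
      p <- groupPost(idx, if (inPlus) +1 else -1)
      mns[g] <- p["mean"]; sds[g] <- p["sd"]
    }
    out[[j]] <- effectPosterior(postW, mns, sds)
  }
  names(out) <- gene@variantIds
  out
}

#' Collapse test statistic for PTV carriers
#'
#' The frequentist baseline: the scaled mean trait value of the carriers,
#' \eqn{T = \sqrt{n}\,\bar z}, which is standard normal under the null
#' (traits standardized, carriers a fixed set of n individuals). Reports T
#' and the two-sided p-value \eqn{2(1 - \Phi(|T|))}.
#'
#' @param carriers numeric carrier trait values or a
#'   \code{\link{CarrierTraits}}.
#' @return list with elements \code{statistic} and \code{p}.
#' @examples
#' collapseStatistic(c(1.8, 2.2, 1.5))
#' @rdname collapseStatistic
#' @export
setMethod("collapseStatistic", "numeric", function(carriers) {
  if (length(carriers) == 0L)
    stop("the Collapse statistic is undefined with zero carriers")
  if (any(!is.finite(carriers))) stop("carrier trait values must be finite")
  stat <- sqrt(length(carriers)) * mean(carriers)
  list(statistic = stat, p = 2 * stats::pnorm(-abs(stat)))
})

#' @rdname collapseStatistic
setMethod("collapseStatistic", "CarrierTraits",
          function(carriers) collapseStatistic(carriers@z))
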