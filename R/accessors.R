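#' Accessors for ptvbayes objects
#'
#' Small accessor functions for the S4 containers; user code should use
#' these rather than reaching into slots.
#'
#' @param x a ptvbayes S4 object.
#' @param level central credible-interval mass (default 0.95).
#' @return The corresponding slot content or derived summary.
#' @name accessors
NULL

#' @rdname accessors
setMethod("traitValues", "CohortTraits", function(x) x@values)
#' @rdname accessors
setMethod("sampleIds", "CohortTraits", function(x) x@sampleIds)
#' @rdname accessors
setMethod("nSamples", "CohortTraits", function(x) length(x@values))

#' @rdname accessors
setMethod("carrierValues", "CarrierTraits", function(x) x@z)
#' @rdname accessors
setMethod("carrierIndex", "CarrierTraits", function(x) x@carrierIndex)
#' @rdname accessors
setMethod("nCarriers", "CarrierTraits", function(x) length(x@z))
#' @rdname accessors
setMethod("nCarriers", "GeneCarrierSet",
          function(x) length(unlist(x@carriers, use.names = FALSE)))

#' @rdname accessors
setMethod("geneId", "GeneCarrierSet", function(x) x@geneId)
#' @rdname accessors
setMethod("variantIds", "GeneCarrierSet", function(x) x@variantIds)
#' @rdname accessors
setMethod("nVariants", "GeneCarrierSet", function(x) length(x@variantIds))
#' @rdname accessors
setMethod("nmdFlags", "GeneCarrierSet",
          function(x) stats::setNames(x@nmd, x@variantIds))
#' @rdname accessors
setMethod("carrierIndex", "GeneCarrierSet",
          function(x) stats::setNames(x@carriers, x@variantIds))

#' @rdname accessors
setMethod("logBF", "BFResult", function(x) x@logBF)
#' @rdname accessors
setMethod("bf", "BFResult", function(x) exp(x@logBF))
#' @rdname accessors
setMethod("perGrouping", "BFResult", function(x) x@perGrouping)
#' @rdname accessors
setMethod("effectPosteriors", "BFResult", function(x) x@posterior)

#' @rdname accessors
setMethod("groupingWeights", "GroupingScheme", function(x) x@weights)
#' @rdname accessors
setMethod("groupingAssignments", "GroupingScheme", function(x) x@assignments)

#' @rdname accessors
setMethod("posteriorMean", "EffectPosterior",
          function(x) sum(x@weights * x@means))

#' @rdname accessors
setMethod("credibleInterval", "EffectPosterior", function(x, level = 0.95) {
  stopifnot(level > 0, level < 1)
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  vapply(probs, function(p) mixtureNormalQuantile(p, x), numeric(1))
})

#' Mixture-of-normals distribution helpers
#'
#' Density, distribution function and quantiles of an
#' \code{\link{EffectPosterior}} mixture; used for credible intervals and
#' for exporting posterior-density tables for plotting.
#'
#' @param q,p numeric quantile / probability.
#' @param post an \code{EffectPosterior}.
#' @return numeric vector.
#' @keywords internal
mixtureNormalCdf <- function(q, post) {
  out <- 0
  for (j in seq_along(post@weights))
    out <- out + post@weights[j] * stats::pnorm(q, post@means[j], post@sds[j])
  out
}

#' @rdname mixtureNormalCdf
#' @keywords internal
mixtureNormalDensity <- function(q, post) {
  out <- 0
  for (j in seq_along(post@weights))
    out <- out + post@weights[j] * stats::dnorm(q, post@means[j], post@sds[j])
  out
}

#' @rdname mixtureNormalCdf
#' @keywords internal
mixtureNormalQuantile <- function(p, post) {
  lo <- min(post@means - 10 * post@sds)
  hi <- max(post@means + 10 * post@sds)
  stats::uniroot(function(q) mixtureNormalCdf(q, post) - p,
                 c(lo, hi), tol = 1e-10)$root
}
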