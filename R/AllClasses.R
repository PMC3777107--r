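#' @import methods
NULL

#' Model hyperparameters for the PTV effect priors
#'
#' Prior location and scale for the carrier mean-shift priors used by the
#' similar-effects model (SEM) and the grouped-effects model (GEM). Under the
#' SEM the mean shift \eqn{\mu} has a 50:50 mixture prior
#' \eqn{0.5\,N(\mu_0,\sigma_0^2) + 0.5\,N(-\mu_0,\sigma_0^2)}; under the GEM
#' the two group means have priors \eqn{N(+\mu_0,\sigma_0^2)} and
#' \eqn{N(-\mu_0,\sigma_0^2)}. The carrier sampling standard deviation
#' \code{s} is fixed at 1 (traits are standardized).
#'
#' @slot mu0 prior component mean magnitude, in trait SD units.
#' @slot sigma0Sq prior component variance, in squared SD units.
#' @slot s carrier sampling standard deviation (fixed 1 unless overridden).
#' @export
setClass("ModelHyperparameters",
  representation(mu0 = "numeric", sigma0Sq = "numeric", s = "numeric"),
  prototype(mu0 = 1.5, sigma0Sq = 0.5, s = 1))

setValidity("ModelHyperparameters", function(object) {
  msg <- character()
  if (length(object@mu0) != 1L || !is.finite(object@mu0) || object@mu0 <= 0)
    msg <- c(msg, "'mu0' must be a single positive finite number")
  if (length(object@sigma0Sq) != 1L || !is.finite(object@sigma0Sq) ||
      object@sigma0Sq <= 0)
    msg <- c(msg, "'sigma0Sq' must be a single positive finite number")
  if (length(object@s) != 1L || !is.finite(object@s) || object@s <= 0)
    msg <- c(msg, "'s' must be a single positive finite number")
  if (length(msg)) msg else TRUE
})

#' @param mu0 prior component mean magnitude (SD units); default 1.5.
#' @param sigma0Sq prior component variance (SD^2 units); default 0.5.
#' @param s carrier sampling SD; fixed at 1 by default.
#' @return A \code{ModelHyperparameters} object.
#' @rdname ModelHyperparameters-class
#' @examples
#' modelHyper()
#' modelHyper(mu0 = 2, sigma0Sq = 1)
#' @export
modelHyper <- function(mu0 = 1.5, sigma0Sq = 0.5, s = 1) {
  new("ModelHyperparameters", mu0 = mu0, sigma0Sq = sigma0Sq, s = s)
}

setMethod("show", "ModelHyperparameters", function(object) {
  cat("ModelHyperparameters: mu0 =", object@mu0,
      " sigma0Sq =", object@sigma0Sq, " s =", object@s, "\n")
})

#' Standardized trait values for a cohort
#'
#' Container for the standardized quantitative trait values \eqn{y_1..y_N}
#' of all N individuals in the cohort. Values are expected to be on the
#' standard-normal scale; \code{\link{quantileNormalize}} produces them from
#' raw measurements.
#'
#' @slot values numeric vector of standardized trait values (unitless SD scale).
#' @slot sampleIds character vector of sample identifiers, same length.
#' @export
setClass("CohortTraits",
  representation(values = "numeric", sampleIds = "character"))

setValidity("CohortTraits", function(object) {
  msg <- character()
  if (length(object@values) != length(object@sampleIds))
    msg <- c(msg, "'values' and 'sampleIds' must have equal length")
  if (any(!is.finite(object@values)))
    msg <- c(msg, "trait values must be finite")
  if (anyDuplicated(object@sampleIds))
    msg <- c(msg, "sample identifiers must be unique")
  if (length(msg)) msg else TRUE
})

#' @param values numeric vector of standardized trait values.
#' @param sampleIds sample identifiers; defaults to \code{S1..SN}.
#' @return A \code{CohortTraits} object.
#' @rdname CohortTraits-class
#' @export
cohortTraits <- function(values,
                         sampleIds = paste0("S", seq_along(values))) {
  new("CohortTraits", values = as.numeric(values),
      sampleIds = as.character(sampleIds))
}

setMethod("show", "CohortTraits", function(object) {
  cat("CohortTraits with", length(object@values), "individuals\n")
  cat("  mean =", signif(mean(object@values), 4),
      " sd =", signif(stats::sd(object@values), 4), "\n")
})

#' Trait values of the PTV carriers in one gene
#'
#' The carrier-side sufficient data for the Bayes factors: the vector z of
#' trait values of the n individuals carrying a PTV in the gene (index set I
#' within the cohort). Both the SEM and the Collapse statistic depend on the
#' data only through (n, mean(z)).
#'
#' @slot z numeric vector of carrier trait values (SD units).
#' @slot carrierIndex integer positions of the carriers within the cohort.
#' @export
setClass("CarrierTraits",
  representation(z = "numeric", carrierIndex = "integer"))

setValidity("CarrierTraits", function(object) {
  msg <- character()
  if (length(object@carrierIndex) &&
      length(object@z) != length(object@carrierIndex))
    msg <- c(msg, "'z' and 'carrierIndex' must have equal length")
  if (any(!is.finite(object@z)))
    msg <- c(msg, "carrier trait values must be finite")
  if (anyDuplicated(object@carrierIndex))
    msg <- c(msg, "an individual may appear at most once among carriers")
  if (length(msg)) msg else TRUE
})

#' @param z numeric carrier trait values.
#' @param carrierIndex optional integer positions within the cohort.
#' @return A \code{CarrierTraits} object.
#' @rdname CarrierTraits-class
#' @export
carrierTraits <- function(z, carrierIndex = integer()) {
  new("CarrierTraits", z = as.numeric(z),
      carrierIndex = as.integer(carrierIndex))
}

setMethod("show", "CarrierTraits", function(object) {
  cat("CarrierTraits: n =", length(object@z),
      " mean(z) =", signif(mean(object@z), 4), "\n")
})

#' Per-gene PTV list with carriers and NMD flags
#'
#' Describes the k PTVs observed in one gene: for each variant, the cohort
#' indices of its carriers and its predicted nonsense-mediated-decay status
#' ("trigger" or "escape", the sets I1 and I0). Carrier sets are disjoint
#' across variants (each individual carries at most one PTV in the gene;
#' multi-carriers are resolved upstream by \code{\link{extractGeneCarriers}}).
#'
#' @slot geneId gene identifier.
#' @slot variantIds identifiers of the k variants.
#' @slot carriers list of integer vectors, cohort indices per variant.
#' @slot nmd character vector, "trigger"/"escape" (or NA when unclassified).
#' @export
setClass("GeneCarrierSet",
  representation(geneId = "character", variantIds = "character",
                 carriers = "list", nmd = "character"))

setValidity("GeneCarrierSet", function(object) {
  msg <- character()
  k <- length(object@variantIds)
  if (k < 1L) msg <- c(msg, "a gene must contain at least one variant (k >= 1)")
  if (length(object@carriers) != k || length(object@nmd) != k)
    msg <- c(msg, "'variantIds', 'carriers' and 'nmd' lengths must agree")
  idx <- unlist(object@carriers, use.names = FALSE)
  if (anyDuplicated(idx))
    msg <- c(msg, "carrier sets must be disjoint across variants")
  bad <- !(object@nmd %in% c("trigger", "escape") | is.na(object@nmd))
  if (any(bad)) msg <- c(msg, "'nmd' entries must be 'trigger', 'escape' or NA")
  if (length(msg)) msg else TRUE
})

#' @param geneId gene identifier.
#' @param variantIds identifiers of the variants.
#' @param carriers list of integer vectors of carrier indices per variant.
#' @param nmd character vector of NMD flags ("trigger"/"escape"), or NA.
#' @return A \code{GeneCarrierSet} object.
#' @rdname GeneCarrierSet-class
#' @export
geneCarrierSet <- function(geneId, variantIds, carriers,
                           nmd = rep(NA_character_, length(variantIds))) {
  new("GeneCarrierSet", geneId = as.character(geneId),
      variantIds = as.character(variantIds),
      carriers = lapply(carriers, as.integer), nmd = as.character(nmd))
}

setMethod("show", "GeneCarrierSet", function(object) {
  n <- length(unlist(object@carriers, use.names = FALSE))
  cat("GeneCarrierSet", object@geneId, ": k =", length(object@variantIds),
      "variants, n =", n, "carriers\n")
  cat("  NMD:", paste0(object@variantIds, "=", object@nmd, collapse = ", "),
      "\n")
})

#' Assignments of variants to the two effect groups
#'
#' A set of groupings g, each assigning all k variants of a gene to the
#' labels "+" and "-", together with nonnegative weights w_g summing to 1.
#' The grouped-effects model Bayes factor is the w-weighted mixture of the
#' per-grouping Bayes factors. Rows of \code{assignments} are groupings;
#' \code{TRUE} places a variant in the "+" group.
#'
#' @slot assignments logical matrix (groupings x variants); TRUE means "+".
#' @slot weights numeric weights per grouping; length 0 while unset.
#' @export
setClass("GroupingScheme",
  representation(assignments = "matrix", weights = "numeric"))

setValidity("GroupingScheme", function(object) {
  msg <- character()
  if (!is.logical(object@assignments))
    msg <- c(msg, "'assignments' must be a logical matrix")
  nw <- length(object@weights)
  if (nw && nw != nrow(object@assignments))
    msg <- c(msg, "one weight per grouping is required")
  if (nw) {
    if (any(object@weights < 0)) msg <- c(msg, "weights must be nonnegative")
    if (abs(sum(object@weights) - 1) > 1e-12)
      msg <- c(msg, "weights must sum to 1 (within 1e-12)")
  }
  if (length(msg)) msg else TRUE
})

#' @param assignments logical matrix, one row per grouping, TRUE = "+" group.
#' @param weights numeric weights summing to 1, or omitted.
#' @return A \code{GroupingScheme} object.
#' @rdname GroupingScheme-class
#' @export
groupingScheme <- function(assignments, weights = numeric()) {
  new("GroupingScheme", assignments = assignments,
      weights = as.numeric(weights))
}

setMethod("show", "GroupingScheme", function(object) {
  cat("GroupingScheme:", nrow(object@assignments), "groupings of",
      ncol(object@assignments), "variants;",
      if (length(object@weights)) "weighted" else "weights unset", "\n")
})

#' Finite mixture-of-normals posterior for a carrier mean shift
#'
#' The conjugate posterior of a carrier mean shift is an exact finite
#' mixture of normal components (two components for the SEM; one per
#' grouping for model-averaged GEM effects).
#'
#' @slot weights mixture weights, summing to 1.
#' @slot means component means (SD units).
#' @slot sds component standard deviations, all positive.
#' @export
setClass("EffectPosterior",
  representation(weights = "numeric", means = "numeric", sds = "numeric"))

setValidity("EffectPosterior", function(object) {
  msg <- character()
  k <- length(object@weights)
  if (length(object@means) != k || length(object@sds) != k)
    msg <- c(msg, "'weights', 'means', 'sds' must have equal length")
  if (k == 0L) msg <- c(msg, "at least one component is required")
  if (abs(sum(object@weights) - 1) > 1e-12)
    msg <- c(msg, "weights must sum to 1 (within 1e-12)")
  if (any(object@sds <= 0)) msg <- c(msg, "sds must be positive")
  if (length(msg)) msg else TRUE
})

effectPosterior <- function(weights, means, sds) {
  new("EffectPosterior", weights = weights / sum(weights),
      means = means, sds = sds)
}

setMethod("show", "EffectPosterior", function(object) {
  cat("EffectPosterior:", length(object@weights), "normal component(s)\n")
  cat("  posterior mean =", signif(posteriorMean(object), 4), "\n")
  ci <- credibleInterval(object)
  cat("  central 95% interval = [", signif(ci[1], 4), ",",
      signif(ci[2], 4), "]\n")
})

#' Bayes factor result
#'
#' Output of the SEM / GEM Bayes-factor computations: the natural-log Bayes
#' factor (alternative vs null), optionally the per-grouping decomposition
#' (weights, per-grouping log BFs and posterior grouping weights) and an
#' effect-size posterior.
#'
#' @slot logBF natural-log Bayes factor.
#' @slot perGrouping data.frame with one row per grouping (may be empty):
#'   columns \code{grouping}, \code{weight}, \code{log_bf}, \code{post_weight}.
#' @slot posterior an \code{EffectPosterior}, a list of them, or NULL.
#' @export
setClass("BFResult",
  representation(logBF = "numeric", perGrouping = "data.frame",
                 posterior = "ANY"),
  prototype(perGrouping = data.frame(), posterior = NULL))

setValidity("BFResult", function(object) {
  msg <- character()
  if (length(object@logBF) != 1L || !is.finite(object@logBF))
    msg <- c(msg, "'logBF' must be a single finite number")
  if (nrow(object@perGrouping)) {
    need <- c("grouping", "weight", "log_bf", "post_weight")
    if (!all(need %in% names(object@perGrouping)))
      msg <- c(msg, paste("perGrouping must have columns",
                          paste(need, collapse = ", ")))
    else {
      mix <- logSumExp(log(object@perGrouping$weight) +
                       object@perGrouping$log_bf)
      if (abs(mix - object@logBF) > 1e-10 * max(1, abs(object@logBF)))
        msg <- c(msg, "BF must equal the weighted sum of per-grouping BFs")
    }
  }
  if (length(msg)) msg else TRUE
})

bfResult <- function(logBF, perGrouping = data.frame(), posterior = NULL) {
  new("BFResult", logBF = logBF, perGrouping = perGrouping,
      posterior = posterior)
}

setMethod("show", "BFResult", function(object) {
  cat("BFResult: BF =", signif(exp(object@logBF), 6),
      " (log BF =", signif(object@logBF, 6), ")\n")
  if (nrow(object@perGrouping))
    cat("  averaged over", nrow(object@perGrouping), "grouping(s)\n")
})
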