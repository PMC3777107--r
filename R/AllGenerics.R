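#' @rdname accessors
#' @export
setGeneric("traitValues", function(x) standardGeneric("traitValues"))
#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setGeneric("carrierValues", function(x) standardGeneric("carrierValues"))
#' @rdname accessors
#' @export
setGeneric("carrierIndex", function(x) standardGeneric("carrierIndex"))
#' @rdname accessors
#' @export
setGeneric("nCarriers", function(x) standardGeneric("nCarriers"))
#' @rdname accessors
#' @export
setGeneric("geneId", function(x) standardGeneric("geneId"))
#' @rdname accessors
#' @export
setGeneric("variantIds", function(x) standardGeneric("variantIds"))
#' @rdname accessors
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))
#' @rdname accessors
#' @export
setGeneric("nmdFlags", function(x) standardGeneric("nmdFlags"))
#' @rdname accessors
#' @export
setGeneric("logBF", function(x) standardGeneric("logBF"))
#' @rdname accessors
#' @export
setGeneric("bf", function(x) standardGeneric("bf"))
#' @rdname accessors
#' @export
setGeneric("perGrouping", function(x) standardGeneric("perGrouping"))
#' @rdname accessors
#' @export
setGeneric("effectPosteriors", function(x) standardGeneric("effectPosteriors"))
#' @rdname accessors
#' @export
setGeneric("groupingWeights", function(x) standardGeneric("groupingWeights"))
#' @rdname accessors
#' @export
setGeneric("groupingAssignments",
           function(x) standardGeneric("groupingAssignments"))
#' @rdname accessors
#' @export
setGeneric("posteriorMean", function(x) standardGeneric("posteriorMean"))
#' @rdname accessors
#' @export
setGeneric("credibleInterval",
           function(x, level = 0.95) standardGeneric("credibleInterval"))

#' @rdname semLogBF
#' @export
setGeneric("semLogBF",
           function(carriers, hyper = modelHyper())
             standardGeneric("semLogBF"))
#' @rdname semPosteriorMu
#' @export
setGeneric("semPosteriorMu",
           function(carriers, hyper = modelHyper())
             standardGeneric("semPosteriorMu"))
#' @rdname collapseStatistic
#' @export
setGeneric("collapseStatistic",
           function(carriers) standardGeneric("collapseStatistic"))
#' @rdname gemNmdLogBF
#' @export
setGeneric("gemNmdLogBF",
           function(gene, cohort, hyper = modelHyper(), scheme = NULL)
             standardGeneric("gemNmdLogBF"))
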