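## Scenario simulators for power studies and synthetic cohort fixtures.
##
## The stated world: cohorts of N = 2000 individuals with standard-normal
## trait values, 3-5 PTVs per gene each seen in a single carrier, carrier
## values mean-shifted normals with unit variance. Effect defaults are
## +2 SD for NMD-triggering variants and -2 SD for escaping variants.

#' Simulation scenario
#'
#' Describes one generating model for synthetic cohorts:
#' \describe{
#'   \item{\code{similar}}{all carriers shifted by \code{effectTrigger}
#'     (loss-of-function-like, same direction).}
#'   \item{\code{grouped_nmd}}{carriers of NMD-triggering variants shifted
#'     by \code{effectTrigger}, carriers of escaping variants by
#'     \code{effectEscape} (opposite directions by default).}
#'   \item{\code{artifact}}{as \code{similar}, but one of the variants is a
#'     sequencing artifact: its carrier's trait value is standard normal.}
#'   \item{\code{null}}{no gene effect; every value standard normal.}
#' }
#' Each variant is carried by exactly one individual; \code{nEscape}
#' variants (default 1) are annotated as escaping NMD regardless of
#' scenario (annotation is independent of the trait model).
#'
#' @slot name scenario name.
#' @slot nCarriers number of PTV carriers (= variants).
#' @slot NTotal cohort size.
#' @slot effectTrigger mean shift (SD units) for NMD-trigger carriers.
#' @slot effectEscape mean shift for NMD-escape carriers.
#' @slot nEscape number of variants annotated as escaping NMD.
#' @slot quantileNormalize whether to quantile-normalize the simulated
#'   cohort after drawing trait values.
#' @export
setClass("SimulationScenario",
  representation(name = "character", nCarriers = "integer",
                 NTotal = "integer", effectTrigger = "numeric",
                 effectEscape = "numeric", nEscape = "integer",
                 quantileNormalize = "logical"))

setValidity("SimulationScenario", function(object) {
  msg <- character()
  if (!object@name %in% c("similar", "grouped_nmd", "artifact", "null"))
    msg <- c(msg, "unknown scenario name")
  if (object@nCarriers < 1L) msg <- c(msg, "nCarriers must be >= 1")
  if (object@nCarriers > object@NTotal)
    msg <- c(msg, "nCarriers must not exceed NTotal")
  if (object@nEscape < 0L || object@nEscape > object@nCarriers)
    msg <- c(msg, "nEscape must be between 0 and nCarriers")
  if (object@name == "artifact" && object@nCarriers < 2L)
    msg <- c(msg, "the artifact scenario needs at least 2 carriers")
  if (length(msg)) msg else TRUE
})

#' @param name scenario name; one of \code{"similar"}, \code{"grouped_nmd"},
#'   \code{"artifact"}, \code{"null"}.
#' @param nCarriers number of PTV carriers (3-5 typical).
#' @param NTotal cohort size (default 2000).
#' @param effectTrigger mean shift for trigger carriers (default 2 SD).
#' @param effectEscape mean shift for escape carriers (default -2 SD).
#' @param nEscape number of escape-annotated variants (default 1).
#' @param quantileNormalize quantile-normalize the cohort after simulation.
#' @return A \code{SimulationScenario}.
#' @rdname SimulationScenario-class
#' @examples
#' simulationScenario("grouped_nmd", nCarriers = 4)
#' @export
simulationScenario <- function(name, nCarriers = 5L, NTotal = 2000L,
                               effectTrigger = 2, effectEscape = -2,
                               nEscape = 1L, quantileNormalize = FALSE) {
  new("SimulationScenario", name = name,
      nCarriers = as.integer(nCarriers), NTotal = as.integer(NTotal),
      effectTrigger = effectTrigger, effectEscape = effectEscape,
      nEscape = as.integer(nEscape),
      quantileNormalize = quantileNormalize)
}

setMethod("show", "SimulationScenario", function(object) {
  cat("SimulationScenario '", object@name, "': n = ", object@nCarriers,
      " carriers in N = ", object@NTotal, "\n", sep = "")
  cat("  effects: trigger ", object@effectTrigger, " SD, escape ",
      object@effectEscape, " SD (", object@nEscape, " escape variant(s))",
      if (object@quantileNormalize) "; quantile-normalized" else "", "\n",
      sep = "")
})

# per-variant mean shifts implied by a scenario (variant order: escape
# variants first, then triggers; the artifact is the last variant)
scenarioShifts <- function(scenario) {
  n <- scenario@nCarriers
  esc <- seq_len(n) <= scenario@nEscape
  mu <- switch(scenario@name,
    null = rep(0, n),
    similar = rep(scenario@effectTrigger, n),
    grouped_nmd = ifelse(esc, scenario@effectEscape,
                         scenario@effectTrigger),
    artifact = c(rep(scenario@effectTrigger, n - 1L), 0))
  list(mu = mu, escape = esc)
}

#' Simulate one cohort under a scenario
#'
#' Draws a full cohort: non-carrier trait values i.i.d. N(0, 1), carrier
#' values mean-shifted per the scenario, one carrier per variant, carrier
#' positions sampled uniformly. With \code{quantileNormalize = TRUE} the
#' whole sample is quantile-normalized after drawing (as a real analysis
#' would, compressing extreme carrier values).
#'
#' @param scenario a \code{\link{SimulationScenario}}.
#' @param seed integer seed; same seed gives a bit-identical cohort.
#' @return list with elements \code{cohort} (a \code{\link{CohortTraits}}),
#'   \code{gene} (a \code{\link{GeneCarrierSet}}) and \code{shifts} (true
#'   per-variant mean shifts).
#' @examples
#' sim <- simulateCohort(simulationScenario("similar", nCarriers = 3),
#'                       seed = 1)
#' sim$gene
#' @export
simulateCohort <- function(scenario, seed = NULL) {
  sh <- scenarioShifts(scenario)
  n <- scenario@nCarriers; N <- scenario@NTotal
  withSeed(seed, {
    y <- stats::rnorm(N)
    idx <- sample.int(N, n)
    y[idx] <- y[idx] + sh$mu
    if (scenario@quantileNormalize)
      y <- traitValues(quantileNormalize(y))
    gene <- geneCarrierSet(
      geneId = "simGene",
      variantIds = sprintf("v%d", seq_len(n)),
      carriers = as.list(idx),
      nmd = ifelse(sh$escape, "escape", "trigger"))
    list(cohort = cohortTraits(y), gene = gene, shifts = sh$mu)
  })
}

# vectorized null/alternative draws of per-variant carrier values:
# replicates x n matrix (only valid without quantile normalization,
# where non-carriers do not enter the statistics)
simulateCarrierMatrix <- function(scenario, replicates, seed) {
  sh <- scenarioShifts(scenario)
  n <- scenario@nCarriers
  withSeed(seed, {
    Z <- matrix(stats::rnorm(replicates * n), nrow = replicates)
    sweep(Z, 2L, sh$mu, "+")
  })
}

#' Estimate power of the association tests under a scenario
#'
#' Monte-Carlo power of SEM, GEM-NMD and/or Collapse at level \code{alpha}:
#' the fraction of simulated cohorts in which the method's statistic
#' exceeds its critical value (analytic for SEM and Collapse; a
#' Monte-Carlo critical value from \code{\link{gemCriticalValueMC}} must be
#' supplied for GEM-NMD). SEM and Collapse reject on exactly the same
#' replicates by construction, having the same frequentist behaviour for
#' fixed carrier count.
#'
#' Without quantile normalization only the carrier values are simulated
#' (non-carriers do not enter any of the statistics), which keeps large
#' replicate counts cheap; with \code{quantileNormalize = TRUE} full
#' cohorts are generated.
#'
#' @param scenario a \code{\link{SimulationScenario}}.
#' @param methods subset of \code{c("SEM", "GEM-NMD", "Collapse")}.
#' @param alpha type I error rate (default 0.001).
#' @param replicates Monte-Carlo replicates.
#' @param seed integer seed.
#' @param hyper a \code{\link{ModelHyperparameters}}.
#' @param gemCritical critical BF for GEM-NMD (from
#'   \code{\link{gemCriticalValueMC}}); required when "GEM-NMD" is among
#'   \code{methods}.
#' @return A power report: data.frame with one row per method and columns
#'   \code{scenario}, \code{method}, \code{n_carriers}, \code{power},
#'   \code{se}, \code{replicates}, \code{alpha}, \code{critical_value}.
#' @examples
#' sc <- simulationScenario("similar", nCarriers = 5)
#' estimatePower(sc, c("SEM", "Collapse"), alpha = 0.001,
#'               replicates = 2000, seed = 1)
#' @export
estimatePower <- function(scenario,
                          methods = c("SEM", "Collapse"),
                          alpha = 0.001, replicates = 2000L, seed = 1L,
                          hyper = modelHyper(), gemCritical = NULL) {
  methods <- match.arg(methods, c("SEM", "GEM-NMD", "Collapse"),
                       several.ok = TRUE)
  n <- scenario@nCarriers
  if ("GEM-NMD" %in% methods && is.null(gemCritical))
    stop("GEM-NMD power needs a Monte-Carlo critical value; run ",
         "gemCriticalValueMC() (or the 'calibrate' command) first")
  rej <- list()
  if (scenario@quantileNormalize) {
    stats_ <- replicateStatsQN(scenario, methods, replicates, seed, hyper)
  } else {
    Z <- simulateCarrierMatrix(scenario, replicates, seed)
    stats_ <- list()
    S <- rowSums(Z)
    if (any(c("SEM", "Collapse") %in% methods)) {
      stats_$absT <- abs(S) / sqrt(n)
      stats_$logbf <- semLogBFStats(n, S, hyper)
    }
    if ("GEM-NMD" %in% methods)
      stats_$gemLogbf <- gemLogBFMatrix(Z, scenarioShifts(scenario)$escape,
                                        hyper)
  }
  zc <- stats::qnorm(1 - alpha / 2)
  semCrit <- semCriticalValue(alpha, n, hyper)
  out <- list()
  for (m in methods) {
    r <- switch(m,
      Collapse = stats_$absT > zc,
      SEM = stats_$logbf > log(semCrit),
      `GEM-NMD` = stats_$gemLogbf > log(gemCritical))
    p <- mean(r)
    out[[m]] <- data.frame(
      scenario = scenario@name, method = m, n_carriers = n,
      power = p, se = sqrt(p * (1 - p) / replicates),
      replicates = replicates, alpha = alpha,
      critical_value = switch(m, Collapse = zc, SEM = semCrit,
                              `GEM-NMD` = gemCritical))
  }
  ans <- do.call(rbind, out)
  rownames(ans) <- NULL
  ans
}

# GEM-NMD log BF for each row of a carrier matrix under the default
# NMD-informed scheme (one carrier per variant)
gemLogBFMatrix <- function(Z, escape, hyper) {
  n <- ncol(Z)
  scheme <- enumerateGroupings(n, "nmd_default", nmdTrigger = !escape)
  asg <- scheme@assignments; w <- scheme@weights
  acc <- matrix(-Inf, nrow = nrow(Z), ncol = nrow(asg))
  for (g in seq_len(nrow(asg))) {
    a <- asg[g, ]
    Sp <- if (any(a)) rowSums(Z[, a, drop = FALSE]) else numeric(nrow(Z))
    Sm <- if (any(!a)) rowSums(Z[, !a, drop = FALSE]) else numeric(nrow(Z))
    acc[, g] <- log(w[g]) +
      logMarginalRatioVec(sum(a), Sp, +hyper@mu0, hyper@sigma0Sq) +
      logMarginalRatioVec(sum(!a), Sm, -hyper@mu0, hyper@sigma0Sq)
  }
  m <- apply(acc, 1L, max)
  m + log(rowSums(exp(acc - m)))
}

# full-cohort replicate statistics when quantile normalization is on
replicateStatsQN <- function(scenario, methods, replicates, seed, hyper) {
  n <- scenario@nCarriers
  absT <- logbf <- gemLogbf <- numeric(replicates)
  for (r in seq_len(replicates)) {
    sim <- simulateCohort(scenario, seed = seed + r - 1L)
    z <- traitValues(sim$cohort)[unlist(carrierIndex(sim$gene),
                                        use.names = FALSE)]
    S <- sum(z)
    absT[r] <- abs(S) / sqrt(n)
    logbf[r] <- semLogBFStats(n, S, hyper)
    if ("GEM-NMD" %in% methods)
      gemLogbf[r] <- logBF(gemNmdLogBF(sim$gene, sim$cohort, hyper))
  }
  list(absT = absT, logbf = logbf, gemLogbf = gemLogbf)
}

#' Power loss from a mislabelled PTV
#'
#' Compares the power of the tests on a clean similar-effects gene against
#' the same gene in which one variant is a sequencing artifact (its
#' carrier's trait value is standard normal despite the PTV label).
#'
#' @param scenario a \code{\link{SimulationScenario}}; its effect sizes and
#'   carrier count define the matched clean/artifact pair (the name is
#'   overridden).
#' @inheritParams estimatePower
#' @return data.frame stacking the clean and artifact power reports, with
#'   an extra column \code{condition} and, per method, the power drop
#'   \code{power_drop} and its standard error \code{power_drop_se}.
#' @examples
#' sc <- simulationScenario("similar", nCarriers = 5)
#' artifactRobustness(sc, alpha = 0.001, replicates = 2000, seed = 1)
#' @export
artifactRobustness <- function(scenario,
                               methods = c("SEM", "Collapse"),
                               alpha = 0.001, replicates = 2000L,
                               seed = 1L, hyper = modelHyper(),
                               gemCritical = NULL) {
  clean <- methods::initialize(scenario, name = "similar")
  dirty <- methods::initialize(scenario, name = "artifact")
  a <- estimatePower(clean, methods, alpha, replicates, seed, hyper,
                     gemCritical)
  b <- estimatePower(dirty, methods, alpha, replicates, seed + 1L, hyper,
                     gemCritical)
  a$condition <- "clean"; b$condition <- "artifact"
  drop <- a$power - b$power
  dropSe <- sqrt(a$se^2 + b$se^2)
  a$power_drop <- b$power_drop <- drop
  a$power_drop_se <- b$power_drop_se <- dropSe
  rbind(a, b)
}
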