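# Closed-form Bayes factors and posteriors against independent quadrature
# oracles, plus the structural identities of the models.

test_that("SEM Bayes factor matches adaptive quadrature on small genes", {
  # spec'd instance first
  z <- c(1.0, 1.5, 2.0)
  expect_lt(relErr(bf(semLogBF(z)), semBFQuad(z)), 1e-8)

  set.seed(11)
  for (i in 1:30) {
    z <- randomCarriers()
    expect_lt(relErr(bf(semLogBF(z)), semBFQuad(z)), 1e-8)
  }

  # non-default hyperparameters go through the same closed form
  h <- modelHyper(mu0 = 2.2, sigma0Sq = 1.3)
  z <- rnorm(6, 1)
  expect_lt(relErr(bf(semLogBF(z, h)), semBFQuad(z, 2.2, 1.3)), 1e-8)
})

test_that("SEM BF is a symmetric function of (n, mean(z)) only", {
  set.seed(21)
  for (i in 1:20) {
    z <- randomCarriers(n = sample(2:10, 1))
    lb <- logBF(semLogBF(z))
    expect_equal(logBF(semLogBF(sample(z))), lb, tolerance = 1e-12)
    # any other vector with the same length and mean
    z2 <- rnorm(length(z)); z2 <- z2 - mean(z2) + mean(z)
    expect_equal(logBF(semLogBF(z2)), lb, tolerance = 1e-12)
    # prior symmetry
    expect_equal(logBF(semLogBF(-z)), lb, tolerance = 1e-12)
  }
  # strictly increasing in |mean(z)| for fixed n
  means <- seq(0, 4, by = 0.25)
  lbf <- vapply(means, function(m) logBF(semLogBF(rep(m, 4))), numeric(1))
  expect_true(all(diff(lbf) > 0))
})

test_that("SEM BF degenerate inputs are handled", {
  expect_warning(res <- semLogBF(numeric(0)), "no PTV carriers")
  expect_equal(bf(res), 1)
  expect_error(semLogBF(c(1, NA)), "finite")
  expect_error(semLogBF(c(1, Inf)), "finite")
})

test_that("SEM posterior is the exact conjugate mixture", {
  # grid-quadrature oracle at the spec'd instance (n = 5, mean -1.2)
  z <- c(-1.0, -1.4, -1.2, -1.3, -1.1)
  post <- semPosteriorMu(z)
  expect_equal(posteriorMean(post), semPosteriorMeanGrid(z),
               tolerance = 1e-6)

  # component moments as stated by the conjugate algebra
  n <- length(z); A <- n + 1 / 0.5
  expect_equal(sort(post@means),
               sort(c((sum(z) + 3) / A, (sum(z) - 3) / A)),
               tolerance = 1e-12)
  expect_equal(post@sds, rep(sqrt(1 / A), 2), tolerance = 1e-12)

  # symmetry: zero mean -> zero posterior mean
  expect_equal(posteriorMean(semPosteriorMu(c(-1, 1, -2, 2))), 0,
               tolerance = 1e-12)
  # likelihood dominance: large n pins the posterior at the carrier mean
  expect_equal(posteriorMean(semPosteriorMu(rep(0.7, 5000))), 0.7,
               tolerance = 1e-3)
  # n = 0 returns the prior
  prior <- semPosteriorMu(numeric(0))
  expect_equal(sort(prior@means), c(-1.5, 1.5))
  expect_equal(prior@weights, c(0.5, 0.5))
})

test_that("credible intervals invert the mixture CDF", {
  z <- c(-1.0, -1.4, -1.2, -1.3, -1.1)
  post <- semPosteriorMu(z)
  ci <- credibleInterval(post)
  expect_equal(ptvbayes:::mixtureNormalCdf(ci[1], post), 0.025,
               tolerance = 1e-8)
  expect_equal(ptvbayes:::mixtureNormalCdf(ci[2], post), 0.975,
               tolerance = 1e-8)
})

test_that("single-grouping GEM factorizes over groups", {
  # spec'd split {1,2} -> +, {3} -> -
  expect_lt(relErr(bf(gemLogBFSingle(c(1.2, 0.8), c(-1.5))),
                   gemBFQuad(c(1.2, 0.8), c(-1.5))), 1e-8)
  # empty groups contribute factor 1
  expect_equal(bf(gemLogBFSingle(numeric(0), numeric(0))), 1)
  z <- c(0.4, 1.1)
  expect_lt(relErr(bf(gemLogBFSingle(z, numeric(0))),
                   gemBFQuad(z, numeric(0))), 1e-8)

  # the two all-same groupings average back to the SEM
  set.seed(31)
  for (i in 1:20) {
    z <- randomCarriers()
    sem <- bf(semLogBF(z))
    mix <- 0.5 * bf(gemLogBFSingle(z, numeric(0))) +
      0.5 * bf(gemLogBFSingle(numeric(0), z))
    expect_equal(mix, sem, tolerance = 1e-12)
  }
})

test_that("grouping enumeration covers the stated modes", {
  expect_equal(nrow(groupingAssignments(enumerateGroupings(3, "full"))), 8)
  expect_error(enumerateGroupings(21, "full"), "k <= 20")

  allSame <- enumerateGroupings(4, "all_same")
  expect_equal(groupingWeights(allSame), c(0.5, 0.5))

  # degenerate NMD partition merges to the SEM scheme
  s1 <- enumerateGroupings(1, "nmd_default", nmdTrigger = TRUE)
  expect_equal(nrow(groupingAssignments(s1)), 2)
  expect_equal(groupingWeights(s1), c(0.5, 0.5))

  s2 <- enumerateGroupings(2, "nmd_default", nmdTrigger = c(TRUE, FALSE))
  expect_equal(nrow(groupingAssignments(s2)), 4)
  expect_equal(groupingWeights(s2), rep(0.25, 4))
  expect_equal(sum(groupingWeights(s2)), 1, tolerance = 1e-12)

  expect_error(enumerateGroupings(2, "nmd_default"), "nmdTrigger")
})

test_that("GEM-NMD mixes groupings and reduces to the SEM when due", {
  coh <- cohortTraits(c(1.8, -1.6, 0.4, -0.2, 0.9))

  # one trigger / one escape carrier: brute-force quadrature oracle
  gene <- geneCarrierSet("G", c("v1", "v2"), list(1L, 2L),
                         nmd = c("trigger", "escape"))
  res <- gemNmdLogBF(gene, coh)
  scheme <- enumerateGroupings(2, "nmd_default",
                               nmdTrigger = c(TRUE, FALSE))
  oracle <- gemNmdBFQuad(carrierIndex(gene), traitValues(coh), scheme)
  expect_lt(relErr(bf(res), oracle), 1e-8)
  expect_equal(sum(perGrouping(res)$post_weight), 1, tolerance = 1e-10)

  # all variants trigger NMD -> exactly the SEM
  geneT <- geneCarrierSet("G", c("v1", "v2", "v3"), list(1L, 2L, 3L),
                          nmd = rep("trigger", 3))
  z <- traitValues(coh)[1:3]
  expect_equal(logBF(gemNmdLogBF(geneT, coh)), logBF(semLogBF(z)),
               tolerance = 1e-12)

  # explicit all-same scheme -> the SEM for any NMD pattern
  gene2 <- geneCarrierSet("G", c("v1", "v2"), list(c(1L, 4L), 2L),
                          nmd = c("trigger", "escape"))
  z2 <- traitValues(coh)[c(1, 4, 2)]
  expect_equal(logBF(gemNmdLogBF(gene2, coh,
                                 scheme = enumerateGroupings(2, "all_same"))),
               logBF(semLogBF(z2)), tolerance = 1e-12)

  # weights are mandatory and must sum to one
  bad <- groupingScheme(rbind(c(TRUE, FALSE)))
  expect_error(gemNmdLogBF(gene, coh, scheme = bad), "weights")
  expect_error(groupingScheme(rbind(c(TRUE, FALSE), c(FALSE, TRUE)),
                              weights = c(0.7, 0.7)), "sum to 1")

  # symmetry of the default scheme: BF(z) == BF(-z)
  expect_equal(logBF(gemNmdLogBF(gene, cohortTraits(-traitValues(coh)))),
               logBF(res), tolerance = 1e-12)
})

test_that("full-scheme GEM is invariant to variant relabelling", {
  set.seed(41)
  coh <- cohortTraits(rnorm(8))
  carriers <- list(1L, c(2L, 3L), 4L, c(5L, 6L))
  full <- enumerateGroupings(4, "full")
  uni <- groupingScheme(groupingAssignments(full),
                        weights = rep(1 / 16, 16))
  gene <- geneCarrierSet("G", paste0("v", 1:4), carriers)
  perm <- c(3L, 1L, 4L, 2L)
  genePerm <- geneCarrierSet("G", paste0("v", 1:4), carriers[perm])
  expect_equal(logBF(gemNmdLogBF(genePerm, coh, scheme = uni)),
               logBF(gemNmdLogBF(gene, coh, scheme = uni)),
               tolerance = 1e-12)
})

test_that("GEM-NMD model-averaged per-variant posteriors are proper", {
  coh <- cohortTraits(c(1.8, -1.6, 0.4))
  gene <- geneCarrierSet("G", c("v1", "v2"), list(1L, 2L),
                         nmd = c("trigger", "escape"))
  res <- gemNmdLogBF(gene, coh)
  posts <- effectPosteriors(res)
  expect_named(posts, c("v1", "v2"))
  for (p in posts) expect_equal(sum(p@weights), 1, tolerance = 1e-12)
  # the dominant grouping is trigger+/escape-, so v1 leans positive and
  # v2 negative
  expect_gt(posteriorMean(posts$v1), 0)
  expect_lt(posteriorMean(posts$v2), 0)
})

test_that("Collapse statistic is the scaled carrier mean", {
  expect_equal(collapseStatistic(c(-1, 1))$p, 1)
  # by construction: n = 4, mean = qnorm(0.9995)/2 gives p = 0.001
  zbar <- qnorm(1 - 0.001 / 2) / 2
  expect_equal(collapseStatistic(rep(zbar, 4))$p, 0.001,
               tolerance = 1e-12)
  expect_error(collapseStatistic(numeric(0)), "zero carriers")

  # simulation oracle: empirical size at alpha = 0.05 with n = 3
  set.seed(51)
  reps <- 1e5
  Z <- matrix(rnorm(reps * 3), ncol = 3)
  p <- 2 * pnorm(-abs(sqrt(3) * rowMeans(Z)))
  size <- mean(p < 0.05)
  expect_lt(abs(size - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
})
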