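# Phenotype normalization, transcript models, NMD classification, and
# carrier extraction from VCF fixtures.

test_that("quantile normalization maps ranks to exact normal quantiles", {
  out <- traitValues(quantileNormalize(c(3.2, 1.1, -0.4, 7.7, 0.0)))
  expect_equal(out, qnorm(c(0.7, 0.5, 0.1, 0.9, 0.3)), tolerance = 1e-12)

  # rank invariance under monotone transforms
  set.seed(81)
  x <- rlnorm(200)
  expect_equal(traitValues(quantileNormalize(log(x))),
               traitValues(quantileNormalize(x)), tolerance = 1e-12)

  # outliers are compressed to the bounded grid extreme
  x2 <- c(rnorm(99), 1e6)
  expect_equal(max(traitValues(quantileNormalize(x2))),
               qnorm((100 - 0.5) / 100), tolerance = 1e-12)

  # empirical mean equals the exact grid mean (here 0 by symmetry)
  expect_lt(abs(mean(traitValues(quantileNormalize(rnorm(501))))), 1e-8)

  # ties get the mean of their tied ranks' transformed values
  out3 <- traitValues(quantileNormalize(c(1, 2, 2, 3)))
  grid <- qnorm((1:4 - 0.5) / 4)
  expect_equal(out3, c(grid[1], rep(mean(grid[2:3]), 2), grid[4]),
               tolerance = 1e-12)

  # missing handling
  expect_warning(ct <- quantileNormalize(c(1, NA, 3, 2)), "missing")
  expect_equal(nSamples(ct), 3)
  expect_error(quantileNormalize(c(NA_real_, NA_real_)), "non-missing")
})

test_that("quantile-normalized traits pass a normality check", {
  set.seed(82)
  for (x in list(rexp(500), rt(800, df = 2), rcauchy(600))) {
    qn <- traitValues(quantileNormalize(x))
    expect_gt(shapiro.test(qn)$p.value, 0.01)
  }
})

test_that("the 50-bp rule classifies termination positions", {
  # two exons: 600 nt + 300 nt, junction at transcript coordinate 600
  tx <- transcriptModel("tx1", "chr1", "+", c(101, 801), c(700, 1100))

  expect_equal(classifyNmd(500, tx), "trigger")    # 200 nt upstream
  expect_equal(classifyNmd(900, tx), "escape")     # final exon
  expect_equal(classifyNmd(650, tx), "escape")     # exactly 50 upstream
  expect_equal(classifyNmd(649, tx), "trigger")    # 51 upstream
  expect_equal(classifyNmd(670, tx), "escape")     # 30 upstream
  # configurable boundary
  expect_equal(classifyNmd(650, tx, boundary = 40), "trigger")
  # splice-disrupting variants default to trigger
  expect_equal(classifyNmd(700, tx, consequence = "splice_disrupting"),
               "trigger")
  # single-exon transcripts have no junction
  tx1 <- transcriptModel("tx2", "chr1", "+", 101, 700)
  expect_equal(classifyNmd(300, tx1), "escape")
  # off-transcript positions are an error
  expect_error(classifyNmd(750, tx), "outside")
})

test_that("NMD calls are strand-invariant under coordinate mirroring", {
  tx <- transcriptModel("txp", "chr1", "+", c(101, 801), c(700, 1100))
  # mirror around position 1201 so exon order reverses on the minus strand
  m <- function(p) 1201 - p
  txm <- transcriptModel("txm", "chr1", "-",
                         starts = c(m(700), m(1100)),
                         ends = c(m(101), m(801)))
  for (pos in c(150, 500, 649, 650, 700, 801, 1100))
    expect_equal(classifyNmd(m(pos), txm), classifyNmd(pos, tx))
})

test_that("transcript coordinate mapping round-trips on both strands", {
  txs <- list(
    transcriptModel("p", "c", "+", c(11, 101, 301), c(40, 150, 320)),
    transcriptModel("m", "c", "-", c(301, 101, 11), c(320, 150, 40)))
  for (tx in txs) {
    L <- sum(tx@ends - tx@starts + 1)
    for (coord in c(1, 2, 30, 31, 80, L)) {
      g <- ptvbayes:::txCoordToGenomic(tx, coord)
      expect_equal(ptvbayes:::genomicToTxCoord(tx, g), coord)
    }
  }
})

test_that("exon models read identically from TSV and GFF3", {
  dir <- withr::local_tempdir()
  tsv <- file.path(dir, "exons.tsv")
  writeLines(c("transcript\tchrom\tstrand\texon_rank\tstart\tend",
               "txA\tchr1\t+\t1\t101\t700",
               "txA\tchr1\t+\t2\t801\t1100",
               "txB\tchr2\t-\t1\t901\t1000",
               "txB\tchr2\t-\t2\t501\t700"), tsv)
  gff <- file.path(dir, "exons.gff3")
  writeLines(c("##gff-version 3",
               "chr1\ttest\texon\t101\t700\t.\t+\t.\tID=e1;Parent=txA",
               "chr1\ttest\texon\t801\t1100\t.\t+\t.\tID=e2;Parent=txA",
               "chr2\ttest\texon\t901\t1000\t.\t-\t.\tID=e3;Parent=txB",
               "chr2\ttest\texon\t501\t700\t.\t-\t.\tID=e4;Parent=txB"),
             gff)
  a <- readExonModel(tsv)
  b <- readExonModel(gff)
  expect_setequal(names(a), names(b))
  for (id in names(a)) {
    expect_equal(a[[id]]@starts, b[[id]]@starts)
    expect_equal(a[[id]]@strand, b[[id]]@strand)
  }
  # minus-strand transcript is ordered 5' to 3'
  expect_equal(a$txB@starts, c(901, 501))
})

test_that("fixtures round-trip through the readers exactly", {
  set.seed(91)
  for (rep in 1:10) {
    nT <- sample(0:3, 1); nE <- sample(0:2, 1)
    if (nT + nE == 0) nT <- 1
    cfg <- fixtureGene("GENE1", nTrigger = nT, nEscape = nE,
                       carriersPerVariant = sample(1:3, nT + nE,
                                                   replace = TRUE),
                       strand = sample(c("+", "-"), 1))
    fx <- generateFixture(list(cfg, fixtureGene("GENE2", 1, 1)),
                          nSamples = 80, dir = withr::local_tempdir(),
                          seed = rep)
    coh <- quantileNormalize(readPhenotypes(fx$phenotypes))
    ext <- suppressMessages(extractGeneCarriers(
      fx$vcf, readPtvAnnotation(fx$annotation), coh,
      readExonModel(fx$exons)))
    for (g in names(fx$truth)) {
      gene <- ext$genes[[g]]
      truth <- fx$truth[[g]]
      expect_equal(variantIds(gene), names(truth))
      for (v in names(truth)) {
        got <- sampleIds(coh)[carrierIndex(gene)[[v]]]
        expect_setequal(got, truth[[v]]$carriers)
        expect_equal(unname(nmdFlags(gene)[v]), truth[[v]]$nmd)
      }
    }
  }
})

test_that("an empty gene list still yields a valid VCF", {
  fx <- generateFixture(list(), nSamples = 10,
                        dir = withr::local_tempdir(), seed = 1)
  vcf <- VariantAnnotation::readVcf(fx$vcf)
  expect_equal(nrow(vcf), 0)
  expect_equal(ncol(vcf), 10)
})

test_that("carrier extraction enforces the at-most-one-PTV assumption", {
  dir <- withr::local_tempdir()
  samples <- sprintf("S%02d", 1:12)
  hdr <- c("##fileformat=VCFv4.2",
           "##contig=<ID=GENEX,length=2000>",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  gt1 <- rep("0/0", 12); gt1[c(1, 2)] <- "0/1"; gt1[3] <- "1/1"
  gt1[4] <- "./."
  gt2 <- rep("0/0", 12); gt2[c(2, 5)] <- "0/1"
  row <- function(pos, id, gt)
    paste(c("GENEX", pos, id, "C", "T", ".", "PASS", ".", "GT", gt),
          collapse = "\t")
  writeLines(c(hdr, row(201, "vA", gt1), row(901, "vB", gt2)),
             file.path(dir, "g.vcf"))
  writeLines(c("variant_id\tgene\tconsequence\ttranscript\tnmd_override",
               "vA\tGENEX\tstop_gain\ttxX\ttrigger",
               "vB\tGENEX\tstop_gain\ttxX\tescape"),
             file.path(dir, "ann.tsv"))
  coh <- cohortTraits(rnorm(12), samples)
  ann <- readPtvAnnotation(file.path(dir, "ann.tsv"))

  # sample S02 carries both variants: excluded by default, with a warning
  expect_warning(
    ext <- suppressMessages(extractGeneCarriers(file.path(dir, "g.vcf"),
                                                ann, coh)),
    ">1 PTV")
  gene <- ext$genes$GENEX
  expect_setequal(carrierIndex(gene)$vA, c(1L, 3L))  # dominant: 1/1 in
  expect_setequal(carrierIndex(gene)$vB, 5L)
  expect_equal(ext$counts$n, 3)

  # first-variant policy keeps the duplicate on its first variant
  ext2 <- suppressMessages(extractGeneCarriers(
    file.path(dir, "g.vcf"), ann, coh, multiPolicy = "first-variant"))
  expect_setequal(carrierIndex(ext2$genes$GENEX)$vA, c(1L, 2L, 3L))
  expect_setequal(carrierIndex(ext2$genes$GENEX)$vB, 5L)

  # homozygotes can be excluded instead of treated dominantly
  expect_warning(ext3 <- suppressMessages(extractGeneCarriers(
    file.path(dir, "g.vcf"), ann, coh, homPolicy = "exclude")), ">1 PTV")
  expect_setequal(carrierIndex(ext3$genes$GENEX)$vA, 1L)

  # NMD overrides took precedence (no transcript model was supplied)
  expect_equal(unname(nmdFlags(gene)), c("trigger", "escape"))
})

test_that("multiallelic records are rejected with guidance", {
  dir <- withr::local_tempdir()
  samples <- c("S1", "S2")
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=G,length=2000>",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", samples),
                     collapse = "\t"),
               paste(c("G", 100, "v1", "C", "T,G", ".", "PASS", ".", "GT",
                       "0/1", "0/2"), collapse = "\t")),
             file.path(dir, "m.vcf"))
  ann <- data.frame(variant_id = "v1", gene = "G",
                    consequence = "stop_gain", transcript = "t",
                    nmd_override = "trigger")
  coh <- cohortTraits(c(0, 1), samples)
  expect_error(extractGeneCarriers(file.path(dir, "m.vcf"), ann, coh),
               "multiallelic")
})

test_that("carrier counts can mirror a two-variant burden gene", {
  # two PTVs with allele counts 1 and 8 -> n = 9 carriers, k = 2
  fx <- generateFixture(
    list(fixtureGene("APOC3like", nTrigger = 2, nEscape = 0,
                     carriersPerVariant = c(1L, 8L),
                     effectTrigger = -1.2,
                     consequence = c("stop_gain", "splice_disrupting"))),
    nSamples = 200, dir = withr::local_tempdir(), seed = 17)
  coh <- quantileNormalize(readPhenotypes(fx$phenotypes))
  ext <- suppressMessages(extractGeneCarriers(
    fx$vcf, readPtvAnnotation(fx$annotation), coh,
    readExonModel(fx$exons)))
  expect_equal(ext$counts$n, 9)
  expect_equal(ext$counts$k, 2)
  ct <- geneCarrierTraits(ext$genes$APOC3like, coh)
  expect_equal(nCarriers(ct), 9)
  # lowered trait values drive the carrier mean negative
  expect_lt(mean(carrierValues(ct)), 0)
})
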