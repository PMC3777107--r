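## Synthetic fixture emitter: writes a minimal consistent trio of files
## (VCF + phenotype TSV + exon-model TSV + PTV annotation TSV) such that
## the readers reconstruct a known ground truth exactly. All output is
## synthetic data.

#' Configuration for a synthetic fixture
#'
#' Builds the per-gene configuration consumed by
#' \code{\link{generateFixture}}. Each gene gets its own contig with a
#' two-exon transcript (single-exon if it has no escaping variants and
#' \code{singleExon = TRUE}); NMD-trigger variants are placed deep in the
#' first exon (more than 50 bases upstream of the junction) and escaping
#' variants in the final exon, so that \code{\link{classifyNmd}} recovers
#' the requested ground truth.
#'
#' @param geneId gene name.
#' @param nTrigger,nEscape numbers of NMD-trigger / NMD-escape variants.
#' @param carriersPerVariant carriers per variant (recycled).
#' @param effectTrigger,effectEscape carrier trait mean shifts (SD units).
#' @param strand transcript strand.
#' @param consequence consequence label for the variants (recycled).
#' @return list describing the gene, for \code{\link{generateFixture}}.
#' @export
fixtureGene <- function(geneId, nTrigger = 2L, nEscape = 1L,
                        carriersPerVariant = 1L,
                        effectTrigger = 2, effectEscape = -2,
                        strand = "+", consequence = "stop_gain") {
  k <- nTrigger + nEscape
  stopifnot(k >= 0L)
  list(geneId = geneId, nTrigger = as.integer(nTrigger),
       nEscape = as.integer(nEscape),
       carriersPerVariant = rep_len(as.integer(carriersPerVariant), k),
       effectTrigger = effectTrigger, effectEscape = effectEscape,
       strand = strand, consequence = rep_len(consequence, k))
}

#' Write a synthetic VCF + phenotype + annotation fixture
#'
#' Emits, under \code{dir}: \code{genotypes.vcf} (VCF v4.2, biallelic
#' SNVs, GT per sample), \code{phenotypes.tsv}
#' (\code{sample_id<TAB>value}), \code{exons.tsv} (6-column exon model)
#' and \code{ptv_annotation.tsv}. Trait values are standard normal with
#' the configured carrier shifts added (raw scale; run
#' \code{\link{quantileNormalize}} downstream as in a real analysis).
#' Carrier sets are disjoint within each gene by construction.
#'
#' @param genes list of gene configurations from \code{\link{fixtureGene}}
#'   (may be empty: a valid sample-only VCF is still written).
#' @param nSamples cohort size.
#' @param dir output directory (created if needed).
#' @param seed integer seed for trait values and carrier placement.
#' @return list with file paths (\code{vcf}, \code{phenotypes},
#'   \code{exons}, \code{annotation}) and \code{truth}, a per-gene list
#'   with the intended carrier sample ids and NMD flags per variant.
#' @examples
#' fx <- generateFixture(list(fixtureGene("GENE1")), nSamples = 50,
#'                       dir = tempfile(), seed = 1)
#' readLines(fx$vcf, n = 8)
#' @export
generateFixture <- function(genes, nSamples, dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  samples <- sprintf("S%03d", seq_len(nSamples))
  totalCarriers <- sum(vapply(genes, function(g)
    sum(g$carriersPerVariant), integer(1)))
  if (totalCarriers > nSamples)
    stop("more carriers requested (", totalCarriers,
         ") than samples (", nSamples, ")")

  truth <- list(); vcfRows <- list(); exonRows <- list(); annRows <- list()
  y <- withSeed(seed, stats::rnorm(nSamples))
  nextCarrier <- 1L

  for (g in genes) {
    k <- g$nTrigger + g$nEscape
    chrom <- g$geneId
    txId <- paste0("tx_", g$geneId)
    # two-exon transcript: 600 nt exon 1, 300 nt exon 2 (plus strand
    # template; minus strand mirrors via transcript coordinates)
    if (g$strand == "+") {
      tx <- transcriptModel(txId, chrom, "+", c(101, 801), c(700, 1100))
    } else {
      tx <- transcriptModel(txId, chrom, "-", c(801, 101), c(1100, 700))
    }
    exonRows[[chrom]] <- data.frame(
      transcript = txId, chrom = chrom, strand = g$strand,
      exon_rank = seq_along(tx@starts),
      start = tx@starts, end = tx@ends)
    # transcript coords: triggers at 100, 120, ... (junction at 600,
    # distance >= 80 > 50); escapes at 650, 670, ... (final exon)
    txCoords <- c(if (g$nTrigger) 100 + 20 * (seq_len(g$nTrigger) - 1L),
                  if (g$nEscape) 650 + 20 * (seq_len(g$nEscape) - 1L))
    flags <- c(rep("trigger", g$nTrigger), rep("escape", g$nEscape))
    geneTruth <- list()
    for (i in seq_len(k)) {
      vid <- sprintf("%s_v%d", g$geneId, i)
      nc <- g$carriersPerVariant[i]
      idx <- seq.int(nextCarrier, length.out = nc)
      nextCarrier <- nextCarrier + nc
      shift <- if (flags[i] == "trigger") g$effectTrigger else
        g$effectEscape
      y[idx] <- y[idx] + shift
      gpos <- txCoordToGenomic(tx, txCoords[i])
      gtv <- rep("0/0", nSamples); gtv[idx] <- "0/1"
      vcfRows[[vid]] <- data.frame(
        CHROM = chrom, POS = gpos, ID = vid, REF = "C", ALT = "T",
        QUAL = ".", FILTER = "PASS", INFO = ".", FORMAT = "GT",
        t(matrix(gtv, dimnames = list(samples, NULL))),
        check.names = FALSE)
      annRows[[vid]] <- data.frame(
        variant_id = vid, gene = g$geneId, consequence = g$consequence[i],
        transcript = txId, nmd_override = NA_character_)
      geneTruth[[vid]] <- list(carriers = samples[idx], nmd = flags[i])
    }
    truth[[g$geneId]] <- geneTruth
  }

  paths <- list(vcf = file.path(dir, "genotypes.vcf"),
                phenotypes = file.path(dir, "phenotypes.tsv"),
                exons = file.path(dir, "exons.tsv"),
                annotation = file.path(dir, "ptv_annotation.tsv"))

  hdr <- c("##fileformat=VCFv4.2",
           "##source=ptvbayes-synthetic-fixture",
           vapply(genes, function(g)
             sprintf("##contig=<ID=%s,length=2000>", g$geneId),
             character(1)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- if (length(vcfRows)) {
    df <- do.call(rbind, vcfRows)
    df <- df[order(df$CHROM, df$POS), , drop = FALSE]
    apply(df, 1L, paste, collapse = "\t")
  } else character(0)
  writeLines(c(hdr, body), paths$vcf)

  utils::write.table(
    data.frame(sample_id = samples, value = y),
    paths$phenotypes, sep = "\t", quote = FALSE, row.names = FALSE)
  exonDf <- if (length(exonRows)) do.call(rbind, exonRows) else
    data.frame(transcript = character(), chrom = character(),
               strand = character(), exon_rank = integer(),
               start = numeric(), end = numeric())
  utils::write.table(exonDf, paths$exons, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (length(annRows))
    utils::write.table(do.call(rbind, annRows), paths$annotation,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  else
    writeLines("variant_id\tgene\tconsequence\ttranscript\tnmd_override",
               paths$annotation)
  c(paths, list(truth = truth, seed = seed))
}
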