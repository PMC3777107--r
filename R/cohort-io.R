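## Reading genotypes, phenotypes and transcript annotation, and turning
## them into the in-memory objects the models consume.

#' Quantile-normalize a quantitative trait
#'
#' Rank-based inverse-normal transform: the value at rank r of N
#' non-missing observations maps to \eqn{\Phi^{-1}((r - 0.5)/N)}, so the
#' transformed trait follows the standard normal distribution exactly at
#' the grid of offset ranks. Ties receive the mean of their tied ranks'
#' transformed values; missing values are excluded (and reported via a
#' warning) and the input order is preserved. Extreme raw values are
#' compressed to at most \eqn{\Phi^{-1}((N - 0.5)/N)}, which is what makes
#' the models robust to phenotype outliers at the cost of some power.
#'
#' @param x numeric vector of raw trait values (any units), possibly with
#'   NAs, or a named vector (names kept as sample identifiers).
#' @param sampleIds optional sample identifiers.
#' @return A \code{\link{CohortTraits}} over the non-missing samples.
#' @examples
#' traitValues(quantileNormalize(c(3.2, 1.1, -0.4, 7.7, 0.0)))
#' @export
quantileNormalize <- function(x, sampleIds = NULL) {
  ids <- sampleIds %||% names(x) %||% paste0("S", seq_along(x))
  keep <- is.finite(x)
  if (!any(keep)) stop("no non-missing trait values to normalize")
  if (sum(keep) < 2L) stop("need at least 2 non-missing values")
  if (any(!keep))
    warning(sum(!keep), " sample(s) with missing trait values excluded")
  x <- x[keep]; ids <- ids[keep]
  N <- length(x)
  grid <- stats::qnorm((seq_len(N) - 0.5) / N)
  rmin <- rank(x, ties.method = "min")
  rmax <- rank(x, ties.method = "max")
  cs <- c(0, cumsum(grid))
  out <- (cs[rmax + 1L] - cs[rmin]) / (rmax - rmin + 1L)
  cohortTraits(out, ids)
}

#' Read a phenotype table
#'
#' Two-column tab-separated file: \code{sample_id<TAB>value}. A header line
#' is detected and skipped; empty fields, \code{NA} and \code{.} are
#' treated as missing.
#'
#' @param path path to the TSV file.
#' @return named numeric vector of raw trait values (NA where missing).
#' @export
readPhenotypes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character",
                          col.names = c("sample_id", "value"))
  if (nrow(df) && suppressWarnings(is.na(as.numeric(df$value[1]))) &&
      !df$value[1] %in% c("", "NA", "."))
    df <- df[-1L, , drop = FALSE]
  vals <- suppressWarnings(as.numeric(df$value))
  vals[df$value %in% c("", "NA", ".")] <- NA_real_
  if (anyDuplicated(df$sample_id)) stop("duplicate sample identifiers")
  stats::setNames(vals, df$sample_id)
}

#' Transcript exon model
#'
#' One transcript's ordered exon structure in genomic coordinates (1-based,
#' inclusive). Exons are stored 5' to 3' in transcript orientation: for a
#' minus-strand transcript the first exon has the highest coordinates.
#'
#' @slot transcriptId transcript identifier.
#' @slot chrom chromosome / contig name.
#' @slot strand \code{"+"} or \code{"-"}.
#' @slot starts,ends exon start/end coordinates, ordered 5' to 3'.
#' @export
setClass("TranscriptModel",
  representation(transcriptId = "character", chrom = "character",
                 strand = "character", starts = "numeric",
                 ends = "numeric"))

setValidity("TranscriptModel", function(object) {
  msg <- character()
  if (!object@strand %in% c("+", "-")) msg <- c(msg, "strand must be + or -")
  k <- length(object@starts)
  if (k < 1L) msg <- c(msg, "at least one exon is required")
  if (length(object@ends) != k) msg <- c(msg, "starts/ends length mismatch")
  if (any(object@ends < object@starts))
    msg <- c(msg, "exon end before start")
  if (k > 1L) {
    ordOk <- if (object@strand == "+")
      all(diff(object@starts) > 0) && all(object@starts[-1L] >
                                          object@ends[-k])
    else
      all(diff(object@starts) < 0) && all(object@ends[-1L] <
                                          object@starts[-k])
    if (!ordOk)
      msg <- c(msg, "exons must be non-overlapping and ordered 5' to 3'")
  }
  if (length(msg)) msg else TRUE
})

#' @param transcriptId transcript identifier.
#' @param chrom chromosome name.
#' @param strand "+" or "-".
#' @param starts,ends exon coordinates, 5' to 3' in transcript orientation.
#' @return A \code{TranscriptModel}.
#' @rdname TranscriptModel-class
#' @export
transcriptModel <- function(transcriptId, chrom, strand, starts, ends) {
  new("TranscriptModel", transcriptId = as.character(transcriptId),
      chrom = as.character(chrom), strand = strand,
      starts = as.numeric(starts), ends = as.numeric(ends))
}

setMethod("show", "TranscriptModel", function(object) {
  cat("TranscriptModel ", object@transcriptId, " (", object@chrom,
      object@strand, "): ", length(object@starts), " exon(s), ",
      sum(object@ends - object@starts + 1), " nt\n", sep = "")
})

# genomic position -> 1-based transcript coordinate (error off-transcript)
genomicToTxCoord <- function(tx, pos) {
  lens <- tx@ends - tx@starts + 1
  cum <- c(0, cumsum(lens))
  for (j in seq_along(lens)) {
    if (pos >= tx@starts[j] && pos <= tx@ends[j]) {
      off <- if (tx@strand == "+") pos - tx@starts[j] else tx@ends[j] - pos
      return(cum[j] + off + 1)
    }
  }
  stop("position ", pos, " is outside the exons of transcript ",
       tx@transcriptId)
}

# 1-based transcript coordinate -> genomic position
txCoordToGenomic <- function(tx, coord) {
  lens <- tx@ends - tx@starts + 1
  cum <- c(0, cumsum(lens))
  stopifnot(coord >= 1, coord <= sum(lens))
  j <- findInterval(coord - 1, cum, rightmost.closed = FALSE)
  off <- coord - cum[j] - 1
  if (tx@strand == "+") tx@starts[j] + off else tx@ends[j] - off
}

# transcript coordinate of the last base of the penultimate exon (the
# final exon-exon junction); NA for single-exon transcripts
finalJunctionCoord <- function(tx) {
  k <- length(tx@starts)
  if (k < 2L) return(NA_real_)
  sum(tx@ends[-k] - tx@starts[-k] + 1)
}

#' Classify a PTV as triggering or escaping nonsense-mediated decay
#'
#' Applies the 50-bp rule: a premature termination codon more than 50
#' transcript bases upstream of the final exon-exon junction is predicted
#' to trigger NMD; one within 50 bp of the junction, or in the final exon,
#' escapes. Single-exon transcripts have no junction, so their PTVs
#' escape. Splice-disrupting variants are treated as NMD triggers by
#' default (the mis-spliced product is assumed degraded); frameshifts use
#' the variant position as a proxy for the termination position.
#'
#' @param pos genomic position of the (proxy) premature termination codon,
#'   1-based; must fall in an exon of \code{tx} unless the consequence is
#'   splice-disrupting.
#' @param tx a \code{\link{TranscriptModel}}.
#' @param consequence one of \code{"stop_gain"}, \code{"frameshift"},
#'   \code{"splice_disrupting"}.
#' @param boundary rule boundary in transcript bases (default 50; distances
#'   strictly greater than it trigger).
#' @return \code{"trigger"} or \code{"escape"}.
#' @examples
#' tx <- transcriptModel("tx1", "chr1", "+", c(101, 801), c(700, 1100))
#' classifyNmd(301, tx)   # deep in exon 1: trigger
#' classifyNmd(900, tx)   # final exon: escape
#' @export
classifyNmd <- function(pos, tx,
                        consequence = c("stop_gain", "frameshift",
                                        "splice_disrupting"),
                        boundary = 50) {
  consequence <- match.arg(consequence)
  if (consequence == "splice_disrupting") return("trigger")
  if (length(tx@starts) < 2L) return("escape")
  coord <- genomicToTxCoord(tx, pos)
  dist <- finalJunctionCoord(tx) - coord
  if (dist > boundary) "trigger" else "escape"
}

#' Read a transcript exon model
#'
#' Accepts either a GFF3/GTF file (exon features with a transcript
#' identifier attribute, imported via \pkg{rtracklayer}) or a 6-column
#' tab-separated table with header
#' \code{transcript<TAB>chrom<TAB>strand<TAB>exon_rank<TAB>start<TAB>end}
#' (1-based inclusive coordinates; \code{exon_rank} is 5'-to-3').
#'
#' @param path path to the annotation file.
#' @return named list of \code{\link{TranscriptModel}} objects.
#' @export
readExonModel <- function(path) {
  if (grepl("\\.(gff3?|gtf)$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path)
    gr <- gr[tolower(as.character(gr$type)) == "exon"]
    md <- S4Vectors::mcols(gr)
    txid <- if ("transcript_id" %in% names(md)) md$transcript_id
            else if ("Parent" %in% names(md))
              vapply(md$Parent, function(p) as.character(p)[1],
                     character(1))
            else stop("no transcript_id/Parent attribute on exon features")
    df <- data.frame(transcript = as.character(txid),
                     chrom = as.character(GenomicRanges::seqnames(gr)),
                     strand = as.character(GenomicRanges::strand(gr)),
                     start = GenomicRanges::start(gr),
                     end = GenomicRanges::end(gr))
  } else {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    need <- c("transcript", "chrom", "strand", "start", "end")
    if (!all(need %in% names(df)))
      stop("exon table needs columns: ", paste(need, collapse = ", "))
    if ("exon_rank" %in% names(df))
      df <- df[order(df$transcript, df$exon_rank), , drop = FALSE]
  }
  out <- lapply(split(df, df$transcript), function(d) {
    strand <- d$strand[1]
    # order exons 5' to 3' in transcript orientation
    o <- order(d$start, decreasing = (strand == "-"))
    transcriptModel(d$transcript[1], d$chrom[1], strand,
                    d$start[o], d$end[o])
  })
  out
}

#' Read a PTV annotation table
#'
#' Tab-separated with header; required columns \code{variant_id},
#' \code{gene}, \code{consequence} (one of stop_gain, frameshift,
#' splice_disrupting), \code{transcript}; optional \code{nmd_override}
#' ("trigger"/"escape") taking precedence over the 50-bp rule.
#'
#' @param path path to the TSV file.
#' @return data.frame of PTV annotations.
#' @export
readPtvAnnotation <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("variant_id", "gene", "consequence", "transcript")
  if (!all(need %in% names(df)))
    stop("annotation needs columns: ", paste(need, collapse = ", "))
  ok <- c("stop_gain", "frameshift", "splice_disrupting")
  if (!all(df$consequence %in% ok))
    stop("consequence must be one of: ", paste(ok, collapse = ", "))
  if (!"nmd_override" %in% names(df)) df$nmd_override <- NA_character_
  df
}

#' Extract per-gene PTV carrier sets from a VCF
#'
#' Reads per-sample genotypes from a VCF (GT field required, biallelic
#' records only — multiallelic sites must be pre-split), intersects samples
#' with the phenotyped cohort, and assembles one
#' \code{\link{GeneCarrierSet}} per annotated gene. A carrier is any
#' individual whose genotype contains at least one alternate allele
#' (dominant coding: heterozygous and homozygous carriers form one class,
#' or homozygotes are excluded with \code{homPolicy = "exclude"}). Missing
#' genotypes (\code{./.}) count as non-carriers (tallied). Individuals
#' carrying more than one PTV in the same gene violate the at-most-one
#' assumption of the models and are excluded from that gene with a warning
#' (\code{multiPolicy = "exclude"}) or attributed to their first variant
#' (\code{"first-variant"}).
#'
#' NMD flags are taken from the annotation's \code{nmd_override} column
#' when present, otherwise computed with \code{\link{classifyNmd}} from
#' the matched transcript in \code{transcripts}.
#'
#' @param vcfPath path to the VCF file (v4.x, GT per sample).
#' @param annotation PTV annotation data.frame
#'   (\code{\link{readPtvAnnotation}}).
#' @param cohort a \code{\link{CohortTraits}} of standardized traits; its
#'   sample order defines carrier indices.
#' @param transcripts named list of \code{\link{TranscriptModel}}s (needed
#'   unless every variant has an NMD override).
#' @param multiPolicy \code{"exclude"} or \code{"first-variant"}.
#' @param homPolicy \code{"dominant"} (default) or \code{"exclude"}.
#' @param boundary 50-bp-rule boundary passed to \code{\link{classifyNmd}}.
#' @return list with \code{genes} (named list of \code{GeneCarrierSet};
#'   genes whose variants have no carriers are dropped) and \code{counts}
#'   (data.frame of N, n, k per gene).
#' @export
extractGeneCarriers <- function(vcfPath, annotation, cohort, transcripts = NULL,
                                multiPolicy = c("exclude", "first-variant"),
                                homPolicy = c("dominant", "exclude"),
                                boundary = 50) {
  multiPolicy <- match.arg(multiPolicy)
  homPolicy <- match.arg(homPolicy)
  vcf <- VariantAnnotation::readVcf(vcfPath)
  if (any(lengths(VariantAnnotation::alt(vcf)) > 1L))
    stop("multiallelic records found: split them (e.g. 'bcftools norm -m-') ",
         "before analysis")
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field")
  vcfSamples <- colnames(gt)
  common <- intersect(sampleIds(cohort), vcfSamples)
  if (!length(common)) stop("no samples shared between VCF and phenotypes")
  pos <- GenomicRanges::start(SummarizedExperiment::rowRanges(vcf))
  vids <- rownames(gt)
  nMissing <- sum(gt %in% c("./.", ".|.", "."))
  if (nMissing)
    message(nMissing, " missing genotype call(s) treated as non-carrier")
  cohortIdx <- stats::setNames(seq_len(nSamples(cohort)), sampleIds(cohort))
  genes <- list(); counts <- list()
  for (g in unique(annotation$gene)) {
    ann <- annotation[annotation$gene == g, , drop = FALSE]
    miss <- setdiff(ann$variant_id, vids)
    if (length(miss))
      stop("annotated variant(s) absent from VCF: ",
           paste(miss, collapse = ", "))
    carriers <- list(); nmd <- character(0); keptIds <- character(0)
    for (i in seq_len(nrow(ann))) {
      vid <- ann$variant_id[i]
      gvec <- gt[vid, common]
      nAlt <- countAltAlleles(gvec)
      keep <- if (homPolicy == "exclude") nAlt == 1L else nAlt >= 1L
      idx <- unname(cohortIdx[common[keep]])
      flag <- ann$nmd_override[i]
      if (is.na(flag)) {
        if (is.null(transcripts) ||
            !ann$transcript[i] %in% names(transcripts))
          stop("no transcript model for ", ann$transcript[i],
               " and no nmd_override for variant ", vid)
        flag <- classifyNmd(pos[match(vid, vids)],
                            transcripts[[ann$transcript[i]]],
                            ann$consequence[i], boundary)
      }
      keptIds <- c(keptIds, vid)
      carriers[[vid]] <- idx
      nmd <- c(nmd, flag)
    }
    # resolve individuals carrying >1 PTV in this gene
    allIdx <- unlist(carriers, use.names = FALSE)
    dup <- unique(allIdx[duplicated(allIdx)])
    if (length(dup)) {
      if (multiPolicy == "exclude") {
        warning(length(dup), " individual(s) carrying >1 PTV in gene ", g,
                " excluded (at-most-one-PTV assumption)")
        carriers <- lapply(carriers, function(ix) setdiff(ix, dup))
      } else {
        seen <- integer(0)
        for (vid in keptIds) {
          carriers[[vid]] <- setdiff(carriers[[vid]], seen)
          seen <- c(seen, carriers[[vid]])
        }
      }
    }
    n <- length(unlist(carriers, use.names = FALSE))
    counts[[g]] <- data.frame(gene = g, N = length(common), n = n,
                              k = length(keptIds))
    if (n > 0L)
      genes[[g]] <- geneCarrierSet(g, keptIds, carriers, nmd)
    else
      message("gene ", g, " has no PTV carriers; skipped")
  }
  list(genes = genes, counts = do.call(rbind, unname(counts)))
}

# number of alternate alleles in a GT string; missing -> 0
countAltAlleles <- function(gt) {
  parts <- strsplit(gt, "[/|]")
  vapply(parts, function(p) sum(p == "1"), integer(1))
}

#' Carrier trait values for one gene
#'
#' Convenience: pull the trait values of a gene's carriers out of the
#' cohort as a \code{\link{CarrierTraits}} object.
#'
#' @param gene a \code{\link{GeneCarrierSet}}.
#' @param cohort a \code{\link{CohortTraits}}.
#' @return A \code{\link{CarrierTraits}}.
#' @export
geneCarrierTraits <- function(gene, cohort) {
  idx <- unlist(carrierIndex(gene), use.names = FALSE)
  carrierTraits(traitValues(cohort)[idx], idx)
}
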