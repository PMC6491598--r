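#' Genomic-feature summary per transcript class
#'
#' Summarizes structural and expression features of lincRNAs, lncNATs and
#' protein-coding transcripts: transcript count, mean exon count, exon-count
#' distribution, fraction spliced (exon count >= 2), median exon length,
#' median mature transcript length, and median expression. The per-transcript
#' expression value is the maximum FPKM over samples, matching the detection
#' criterion used in identification.
#'
#' @param transcripts A \code{TranscriptSet} with biotypes assigned (classes
#'   other than lincRNA/lncNAT/coding are ignored).
#' @param expr A \code{SummarizedExperiment} of FPKM, or \code{NULL} to skip
#'   expression summaries.
#' @return A data.frame with one row per class present in the input and a
#'   list column \code{exon_count_table} holding the exon-count
#'   distribution. Empty classes are absent, not zero-filled.
#' @export
featureSummary <- function(transcripts, expr = NULL) {
  classes <- intersect(c("lincRNA", "lncNAT", "coding"),
                       unique(txBiotype(transcripts)))
  maxfpkm <- NULL
  if (!is.null(expr))
    maxfpkm <- apply(assay(expr, "fpkm"), 1, max)
  rows <- lapply(classes, function(cl) {
    sub <- transcripts[txBiotype(transcripts) == cl]
    ec <- exonCounts(sub)
    exlen <- width(unlist(sub@exons, use.names = FALSE))
    med_fpkm <- NA_real_
    if (!is.null(maxfpkm)) {
      hit <- intersect(txIds(sub), names(maxfpkm))
      if (length(hit)) med_fpkm <- stats::median(maxfpkm[hit])
    }
    data.frame(class = cl,
               n = length(sub),
               mean_exons = mean(ec),
               fraction_spliced = mean(ec >= 2),
               median_exon_length = stats::median(exlen),
               median_tx_length = stats::median(txLengths(sub)),
               median_fpkm = med_fpkm,
               exon_count_table = I(list(table(ec))))
  })
  do.call(rbind, rows)
}

#' Fraction of a lncNAT's bases overlapped by antisense gene loci
#'
#' For each natural antisense transcript, the fraction of its mature
#' (exonic) bases that lie within a reference gene locus on the opposite
#' strand. A lncNAT fully contained in an antisense gene span scores exactly
#' 1; by the lncNAT definition the fraction is strictly positive, so a zero
#' overlap raises an error.
#'
#' @param nat A \code{TranscriptSet} of lncNATs with known strands.
#' @param ref The reference \code{TranscriptSet}.
#' @return Named numeric vector of fractions in (0, 1].
#' @export
antisenseOverlapFraction <- function(nat, ref) {
  genes <- geneRanges(ref)
  out <- vapply(seq_len(length(nat)), function(k) {
    ex <- nat@exons[[k]]
    s <- as.character(strand(ex))[1]
    if (s == "*") stop("lncNAT strand must be known")
    anti <- reduce(genes[as.character(strand(genes)) != s],
                   ignore.strand = TRUE)
    ov <- sum(width(GenomicRanges::intersect(
      reduce(ex, ignore.strand = TRUE), anti, ignore.strand = TRUE)))
    ov / sum(width(ex))
  }, numeric(1))
  names(out) <- txIds(nat)
  if (any(out == 0))
    stop("no antisense overlap for: ",
         paste(names(out)[out == 0], collapse = ", "),
         " (violates lncNAT precondition)")
  out
}

#' Inter-locus distances and intron lengths
#'
#' Computes, at the gene level: (i) the distance from each lncRNA gene to
#' its nearest protein-coding gene on either strand; (ii) distances between
#' consecutive coding genes along each chromosome; and (iii) intron lengths
#' of all coding transcripts. The distance between 1-based inclusive
#' intervals \[a,b\] and \[c,d\] with c > b is c - b - 1 (the count of
#' intervening bases), so touching or overlapping loci are at distance 0.
#' A chromosome carrying a single coding gene contributes no gene-gene
#' interval.
#'
#' @param lncrnas A \code{TranscriptSet} of lncRNAs.
#' @param ref The reference \code{TranscriptSet} of coding genes.
#' @return A list with numeric vectors \code{lnc_to_gene},
#'   \code{gene_to_gene}, \code{intron_lengths} and a named vector
#'   \code{medians}.
#' @export
locusDistances <- function(lncrnas, ref) {
  genes <- geneRanges(ref)
  lnc_genes <- geneRanges(lncrnas)

  d <- GenomicRanges::distanceToNearest(lnc_genes, genes, ignore.strand = TRUE)
  lnc_to_gene <- rep(NA_real_, length(lnc_genes))
  lnc_to_gene[S4Vectors::queryHits(d)] <- mcols(d)$distance
  names(lnc_to_gene) <- names(lnc_genes)

  gg <- unlist(lapply(split(genes, as.character(seqnames(genes))), function(g) {
    if (length(g) < 2L) return(numeric(0))
    g <- g[order(start(g))]
    pmax(0, start(g)[-1] - end(g)[-length(g)] - 1)
  }), use.names = FALSE)

  introns <- width(unlist(intronRanges(ref), use.names = FALSE))

  list(lnc_to_gene = lnc_to_gene,
       gene_to_gene = gg,
       intron_lengths = introns,
       medians = c(lnc_to_gene = stats::median(lnc_to_gene, na.rm = TRUE),
                   gene_to_gene = if (length(gg)) stats::median(gg) else NA_real_,
                   intron_length = if (length(introns)) stats::median(introns)
                                   else NA_real_))
}

#' Two-sample Kolmogorov-Smirnov comparison of expression distributions
#'
#' Standard two-sided two-sample KS test, used both for expression-level
#' comparisons between transcript classes and for comparing Tau-score
#' distributions.
#'
#' @param a,b Non-empty numeric vectors.
#' @return A list with \code{statistic} (the KS D) and \code{p_value}.
#' @export
compareExpressionDistributions <- function(a, b) {
  if (!length(a) || !length(b))
    stop("both samples must be non-empty")
  ks <- suppressWarnings(stats::ks.test(a, b))
  list(statistic = unname(ks$statistic), p_value = unname(ks$p.value))
}
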