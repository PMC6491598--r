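#' @import methods
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
#' @importFrom GenomeInfoDb seqinfo seqlengths seqlevels Seqinfo
NULL

.CLASS_CODES <- c("u", "x", "i", "other", "none")
.BIOTYPES    <- c("coding", "lincRNA", "lncNAT", "candidate", "rejected")

#' TranscriptSet: exon-structured transcript models
#'
#' A container for a set of stranded, exon-structured transcript models on a
#' shared set of chromosomes, used both for the reference protein-coding
#' annotation and for assembled candidate transcripts. Exons are stored as a
#' \linkS4class{GRangesList} (one element per transcript, 1-based inclusive
#' GTF coordinates, exons sorted and non-overlapping within a transcript);
#' per-transcript metadata (gene id, class code, biotype) live in a parallel
#' \code{DataFrame}.
#'
#' Class codes follow the reference-comparison convention: \code{"u"}
#' (intergenic, no overlap with any annotated locus), \code{"x"} (exonic
#' overlap with a reference exon on the opposite strand), \code{"i"} (fully
#' contained within a reference intron), \code{"other"} (any other overlap),
#' \code{"none"} (not yet assigned). Biotypes are \code{"coding"},
#' \code{"lincRNA"}, \code{"lncNAT"}, \code{"candidate"}, \code{"rejected"}.
#'
#' @slot exons A \code{GRangesList}, one element per transcript, names are
#'   transcript ids.
#' @slot txData A \code{DataFrame} with one row per transcript and columns
#'   \code{gene_id}, \code{class_code}, \code{biotype}.
#'
#' @seealso [readAnnotation()], [assignClassCodes()], [filterLncRNA()]
#' @export
setClass("TranscriptSet",
  slots = c(exons = "GRangesList", txData = "DataFrame"))

.validTranscriptSet <- function(object) {
  msg <- character()
  ex <- object@exons
  td <- object@txData
  ids <- names(ex)
  if (is.null(ids) || anyDuplicated(ids))
    msg <- c(msg, "transcript ids must be unique, non-NULL names on 'exons'")
  if (length(ex) != nrow(td) || !identical(ids, rownames(td)))
    msg <- c(msg, "'txData' rownames must match names of 'exons'")
  if (!all(c("gene_id", "class_code", "biotype") %in% colnames(td)))
    msg <- c(msg, "'txData' needs columns gene_id, class_code, biotype")
  if (length(msg))
    return(msg)
  if (!all(td$class_code %in% .CLASS_CODES))
    msg <- c(msg, sprintf("class_code values must be in {%s}",
                          paste(.CLASS_CODES, collapse = ",")))
  if (!all(td$biotype %in% .BIOTYPES))
    msg <- c(msg, sprintf("biotype values must be in {%s}",
                          paste(.BIOTYPES, collapse = ",")))
  if (length(ex)) {
    ul <- unlist(ex, use.names = FALSE)
    if (any(start(ul) < 1L))
      msg <- c(msg, "exon starts must be >= 1 (1-based inclusive coordinates)")
    sl <- seqlengths(ul)
    known <- !is.na(sl[as.character(seqnames(ul))])
    if (any(known) &&
        any(end(ul)[known] > sl[as.character(seqnames(ul))][known]))
      msg <- c(msg, "exon ends exceed declared chromosome lengths")
    # one strand and one chromosome per transcript; exons sorted, disjoint
    nstr <- vapply(ex, function(g)
      length(unique(as.character(strand(g)))), integer(1))
    if (any(nstr != 1L))
      msg <- c(msg, "each transcript must be on a single strand")
    ok <- vapply(ex, function(g) {
      s <- start(g); e <- end(g)
      length(unique(as.character(seqnames(g)))) == 1L &&
        !is.unsorted(s, strictly = TRUE) &&
        (length(g) < 2L || all(s[-1] > e[-length(e)]))
    }, logical(1))
    if (!all(ok))
      msg <- c(msg, "exons within a transcript must be sorted and non-overlapping")
    str1 <- vapply(ex, function(g) as.character(strand(g))[1], character(1))
    bad <- str1 == "*" & !(td$biotype %in% c("candidate", "rejected"))
    if (any(bad))
      msg <- c(msg, "unknown strand is only allowed for candidate/rejected transcripts")
  }
  if (length(msg)) msg else TRUE
}
setValidity("TranscriptSet", .validTranscriptSet)

#' Construct a TranscriptSet
#'
#' @param exons A \code{GRangesList} of exon ranges, one element per
#'   transcript; names are transcript ids. Exons are sorted internally.
#' @param geneId Character vector of gene ids, one per transcript (recycled
#'   if length 1).
#' @param classCode Class codes (default \code{"none"}).
#' @param biotype Biotypes (default \code{"candidate"}).
#' @return A validated \code{TranscriptSet}.
#' @examples
#' gr <- GenomicRanges::GRangesList(
#'   t1 = GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 201), c(100, 300)), "+"))
#' ts <- TranscriptSet(gr, geneId = "g1", biotype = "coding")
#' txLengths(ts)
#' @export
TranscriptSet <- function(exons, geneId,
                          classCode = "none", biotype = "candidate") {
  exons <- GRangesList(lapply(exons, sort), compress = TRUE)
  n <- length(exons)
  td <- DataFrame(
    gene_id    = rep(as.character(geneId), length.out = n),
    class_code = rep(as.character(classCode), length.out = n),
    biotype    = rep(as.character(biotype), length.out = n),
    row.names  = names(exons))
  new("TranscriptSet", exons = exons, txData = td)
}

#' @describeIn TranscriptSet-accessors Number of transcripts.
#' @export
setMethod("length", "TranscriptSet", function(x) length(x@exons))

setMethod("show", "TranscriptSet", function(object) {
  td <- object@txData
  cat(sprintf("TranscriptSet with %d transcripts (%d genes) on %d sequence(s)\n",
              length(object), length(unique(td$gene_id)),
              length(unique(as.character(seqnames(
                unlist(object@exons, use.names = FALSE)))))))
  bt <- table(td$biotype)
  cat("biotypes:", paste(sprintf("%s=%d", names(bt), bt), collapse = " "), "\n")
  cc <- table(td$class_code)
  cat("class codes:", paste(sprintf("%s=%d", names(cc), cc), collapse = " "), "\n")
})

#' Accessors for TranscriptSet
#'
#' Small accessor family: transcript ids, gene ids, class codes, biotypes,
#' exon structure and derived per-transcript quantities. Transcript length is
#' the mature (spliced) length, i.e. the sum of exon widths, not the genomic
#' span.
#'
#' @param x,object A \code{TranscriptSet}.
#' @param value Replacement value.
#' @param i Index, logical vector or character vector of transcript ids.
#' @name TranscriptSet-accessors
NULL

#' @describeIn TranscriptSet-accessors Transcript identifiers.
#' @export
txIds <- function(x) names(x@exons)

#' @describeIn TranscriptSet-accessors Gene identifiers (per transcript).
#' @export
geneIds <- function(x) x@txData$gene_id

#' @describeIn TranscriptSet-accessors Class codes (per transcript).
#' @export
classCode <- function(x) x@txData$class_code

#' @describeIn TranscriptSet-accessors Replace class codes.
#' @export
`classCode<-` <- function(x, value) {
  x@txData$class_code <- rep(as.character(value), length.out = length(x))
  validObject(x)
  x
}

#' @describeIn TranscriptSet-accessors Biotypes (per transcript).
#' @export
txBiotype <- function(x) x@txData$biotype

#' @describeIn TranscriptSet-accessors Replace biotypes.
#' @export
`txBiotype<-` <- function(x, value) {
  x@txData$biotype <- rep(as.character(value), length.out = length(x))
  validObject(x)
  x
}

#' @describeIn TranscriptSet-accessors Exon ranges as a \code{GRangesList}.
#' @export
exonRanges <- function(x) x@exons

#' @describeIn TranscriptSet-accessors Mature transcript lengths (sum of exon
#'   widths, nt).
#' @export
txLengths <- function(x) {
  len <- vapply(width(x@exons), sum, integer(1))
  stats::setNames(as.integer(len), txIds(x))
}

#' @describeIn TranscriptSet-accessors Exon counts per transcript.
#' @export
exonCounts <- function(x)
  stats::setNames(S4Vectors::elementNROWS(x@exons), txIds(x))

#' @describeIn TranscriptSet-accessors Strand per transcript
#'   (\code{"+"}, \code{"-"} or \code{"*"} for unknown).
#' @export
txStrand <- function(x) {
  s <- vapply(x@exons, function(g) as.character(strand(g))[1], character(1))
  stats::setNames(s, txIds(x))
}

#' @describeIn TranscriptSet-accessors Genomic span of each transcript as a
#'   \code{GRanges}.
#' @export
txRanges <- function(x) {
  if (!length(x)) return(GRanges())
  unlist(range(x@exons))
}

#' @describeIn TranscriptSet-accessors Genomic span of each gene (union of
#'   its transcripts) as a named \code{GRanges}.
#' @export
geneRanges <- function(x) {
  if (!length(x)) return(GRanges())
  sp <- txRanges(x)
  spl <- split(sp, geneIds(x))
  unlist(range(spl))
}

#' @describeIn TranscriptSet-accessors Intron ranges per transcript (gaps
#'   between consecutive exons) as a \code{GRangesList}.
#' @export
intronRanges <- function(x) {
  ex <- x@exons
  res <- lapply(seq_along(ex), function(k) {
    g <- ex[[k]]
    if (length(g) < 2L) return(GRanges(seqinfo = seqinfo(g)))
    GRanges(seqnames(g)[1],
            IRanges(end(g)[-length(g)] + 1L, start(g)[-1] - 1L),
            strand = strand(g)[1], seqinfo = seqinfo(g))
  })
  names(res) <- txIds(x)
  GRangesList(res, compress = TRUE)
}

#' @describeIn TranscriptSet-accessors Subset by index or transcript id.
#' @export
setMethod("[", "TranscriptSet", function(x, i, ...) {
  ex <- x@exons[i]
  new("TranscriptSet", exons = ex, txData = x@txData[names(ex), , drop = FALSE])
})

#' Combine two TranscriptSets
#'
#' @param x,y \code{TranscriptSet} objects with disjoint transcript ids.
#' @return A \code{TranscriptSet} holding both.
#' @export
combineTranscriptSets <- function(x, y) {
  if (any(txIds(y) %in% txIds(x)))
    stop("transcript ids overlap between the two sets")
  new("TranscriptSet",
      exons = suppressWarnings(c(x@exons, y@exons)),
      txData = rbind(x@txData, y@txData))
}
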