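#' Filter configuration for lncRNA identification
#'
#' Thresholds for the five-criterion lncRNA definition: mature length
#' strictly greater than \code{min_length_nt}; coding-potential (CPC) score
#' strictly below \code{max_cpc_score}; no Pfam protein-domain hit; known
#' strand; and detectable expression in at least one condition
#' (\code{min_fpkm_multiexon} for spliced transcripts,
#' \code{min_fpkm_monoexon} for single-exon transcripts, both inclusive).
#' Single-exon transcripts face the stiffer FPKM cutoff because unspliced,
#' weakly expressed fragments are the dominant assembly artifact class.
#'
#' @param min_length_nt Exclusive length bound in nt (default 200).
#' @param max_cpc_score Strict upper bound on the CPC score (default 0).
#' @param require_no_pfam Drop transcripts with any Pfam hit (default TRUE).
#' @param require_strand Drop transcripts of unknown strand (default TRUE).
#' @param min_fpkm_multiexon Minimum max-FPKM for multi-exon transcripts
#'   (default 0.5, inclusive).
#' @param min_fpkm_monoexon Minimum max-FPKM for single-exon transcripts
#'   (default 2, inclusive).
#' @return A named list of validated thresholds.
#' @export
identificationConfig <- function(min_length_nt = 200,
                                 max_cpc_score = 0,
                                 require_no_pfam = TRUE,
                                 require_strand = TRUE,
                                 min_fpkm_multiexon = 0.5,
                                 min_fpkm_monoexon = 2) {
  cfg <- list(min_length_nt = min_length_nt,
              max_cpc_score = max_cpc_score,
              require_no_pfam = isTRUE(require_no_pfam),
              require_strand = isTRUE(require_strand),
              min_fpkm_multiexon = min_fpkm_multiexon,
              min_fpkm_monoexon = min_fpkm_monoexon)
  num <- unlist(cfg[c("min_length_nt", "max_cpc_score",
                      "min_fpkm_multiexon", "min_fpkm_monoexon")])
  if (any(!is.finite(num)))
    stop("all thresholds must be finite")
  if (cfg$min_fpkm_monoexon < cfg$min_fpkm_multiexon)
    stop("min_fpkm_monoexon must be >= min_fpkm_multiexon")
  cfg
}

#' Assign reference-comparison class codes to candidate transcripts
#'
#' Each candidate receives exactly one code by comparison with the
#' reference annotation: \code{"x"} for at least 1 bp of exonic overlap with
#' a reference exon on the opposite strand; \code{"i"} for a transcript whose
#' genomic span is fully contained within a single reference intron;
#' \code{"u"} for a transcript overlapping no reference gene locus on either
#' strand; \code{"other"} for sense exonic overlap, unstranded exonic
#' overlap, or any partial structure matching none of the above. Exonic
#' overlap takes precedence over intronic containment.
#'
#' @param candidates A \code{TranscriptSet} of assembled candidates.
#' @param ref A \code{TranscriptSet} reference annotation.
#' @return \code{candidates} with \code{classCode()} filled in.
#' @export
assignClassCodes <- function(candidates, ref) {
  cand_chr <- unique(vapply(candidates@exons, function(g)
    as.character(seqnames(g))[1], character(1)))
  ref_chr <- unique(vapply(ref@exons, function(g)
    as.character(seqnames(g))[1], character(1)))
  missing <- setdiff(cand_chr, ref_chr)
  if (length(missing))
    stop("candidate chromosome(s) absent from reference: ",
         paste(missing, collapse = ", "))

  ref_ex <- unlist(ref@exons, use.names = FALSE)
  ref_genes <- geneRanges(ref)
  ref_introns <- unlist(intronRanges(ref), use.names = FALSE)
  spans <- txRanges(candidates)
  cand_strand <- txStrand(candidates)

  n <- length(candidates)
  codes <- rep("other", n)

  # exonic overlap with reference exons, per candidate, strand-resolved
  flat <- unlist(candidates@exons, use.names = FALSE)
  who <- rep(seq_len(n), S4Vectors::elementNROWS(candidates@exons))
  hits <- findOverlaps(flat, ref_ex, ignore.strand = TRUE)
  cs <- cand_strand[who[S4Vectors::queryHits(hits)]]
  rs <- as.character(strand(ref_ex))[S4Vectors::subjectHits(hits)]
  hit_cand <- who[S4Vectors::queryHits(hits)]
  sense <- cs == rs | cs == "*" | rs == "*"
  has_sense <- unique(hit_cand[sense])
  has_anti  <- unique(hit_cand[!sense])
  exonic <- unique(hit_cand)

  codes[exonic] <- "other"                 # sense or ambiguous overlap
  codes[setdiff(has_anti, has_sense)] <- "x"

  # intronic containment (span within one reference intron, either strand)
  inh <- findOverlaps(spans, ref_introns, type = "within",
                      ignore.strand = TRUE)
  intronic <- setdiff(unique(S4Vectors::queryHits(inh)), exonic)
  codes[intronic] <- "i"

  # intergenic: no overlap with any gene locus on either strand
  gh <- findOverlaps(spans, ref_genes, ignore.strand = TRUE)
  touched <- unique(S4Vectors::queryHits(gh))
  codes[setdiff(seq_len(n), touched)] <- "u"

  classCode(candidates) <- codes
  candidates
}

#' Apply the five-criterion lncRNA filter with a per-step audit funnel
#'
#' Candidates pass through, in order: class code in \{u, x, i\}; mature
#' length strictly > 200 nt; CPC coding-potential score strictly < 0; no
#' Pfam domain hit; known strand; and the expression criterion (max FPKM
#' over conditions >= 0.5 for multi-exon, >= 2 for single-exon transcripts).
#' Transcripts that fail only the strand or expression step are returned
#' separately as low-confidence lncRNAs. Expression is evaluated on
#' replicate-collapsed condition means when replicate labels are present.
#'
#' @param candidates A \code{TranscriptSet} with class codes assigned.
#' @param scores A data.frame with columns \code{id}, \code{cpc_score}
#'   (numeric) and \code{pfam_hit} (logical); one row per candidate.
#' @param expr A \code{SummarizedExperiment} of FPKM covering all
#'   candidates.
#' @param cfg Output of [identificationConfig()].
#' @return A list with elements \code{accepted} and \code{low_confidence}
#'   (both \code{TranscriptSet}, biotypes set to \code{"candidate"} and
#'   \code{"rejected"} respectively) and \code{funnel}, a data.frame with
#'   columns \code{step}, \code{n_in}, \code{n_out} and a list column
#'   \code{rejected} of the ids removed at each step.
#' @export
filterLncRNA <- function(candidates, scores, expr,
                         cfg = identificationConfig()) {
  ids <- txIds(candidates)
  miss <- setdiff(ids, scores$id)
  if (length(miss))
    stop("missing score row for transcript(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  miss <- setdiff(ids, rownames(expr))
  if (length(miss))
    stop("missing expression row for transcript(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  sc <- scores[match(ids, scores$id), ]

  if (!all(is.na(colData(expr)$replicate)))
    expr <- collapseReplicates(expr)
  maxfpkm <- apply(assay(expr, "fpkm")[ids, , drop = FALSE], 1, max)

  pass <- list(
    class_code = classCode(candidates) %in% c("u", "x", "i"),
    length     = txLengths(candidates) > cfg$min_length_nt,
    cpc        = sc$cpc_score < cfg$max_cpc_score,
    pfam       = if (cfg$require_no_pfam) !sc$pfam_hit else rep(TRUE, length(ids)),
    strand     = if (cfg$require_strand) txStrand(candidates) != "*"
                 else rep(TRUE, length(ids)),
    expression = ifelse(exonCounts(candidates) >= 2,
                        maxfpkm >= cfg$min_fpkm_multiexon,
                        maxfpkm >= cfg$min_fpkm_monoexon))

  alive <- rep(TRUE, length(ids))
  funnel <- data.frame(step = names(pass),
                       n_in = NA_integer_, n_out = NA_integer_)
  rejected <- vector("list", length(pass))
  for (k in seq_along(pass)) {
    funnel$n_in[k] <- sum(alive)
    drop <- alive & !pass[[k]]
    rejected[[k]] <- ids[drop]
    alive <- alive & pass[[k]]
    funnel$n_out[k] <- sum(alive)
  }
  funnel$rejected <- I(rejected)

  hard <- pass$class_code & pass$length & pass$cpc & pass$pfam
  lowconf <- hard & !(pass$strand & pass$expression)

  accepted <- candidates[alive]
  low <- candidates[lowconf]
  if (length(low)) txBiotype(low) <- "rejected"
  list(accepted = accepted, low_confidence = low, funnel = funnel)
}

#' Partition accepted lncRNAs into lincRNA and lncNAT biotypes
#'
#' A transcript is a long noncoding natural antisense transcript (lncNAT)
#' if and only if its genomic span overlaps a reference coding-gene locus by
#' at least 1 bp on the opposite strand; this covers class \code{"x"} and
#' antisense-intronic \code{"i"} transcripts. All other accepted transcripts
#' (class \code{"u"} and sense-intronic \code{"i"}) are long intergenic
#' noncoding RNAs (lincRNA). The partition is total.
#'
#' @param accepted A stranded \code{TranscriptSet} of accepted lncRNAs.
#' @param ref The reference \code{TranscriptSet}.
#' @return \code{accepted} with \code{txBiotype()} set to \code{"lincRNA"}
#'   or \code{"lncNAT"}.
#' @export
classifyBiotype <- function(accepted, ref) {
  if (!length(accepted)) return(accepted)
  if (any(txStrand(accepted) == "*"))
    stop("accepted transcripts must have known strand")
  spans <- txRanges(accepted)
  genes <- geneRanges(ref)
  hits <- findOverlaps(spans, genes, ignore.strand = TRUE)
  anti <- as.character(strand(spans))[S4Vectors::queryHits(hits)] !=
          as.character(strand(genes))[S4Vectors::subjectHits(hits)]
  is_nat <- seq_along(spans) %in% S4Vectors::queryHits(hits)[anti]
  txBiotype(accepted) <- ifelse(is_nat, "lncNAT", "lincRNA")
  accepted
}
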