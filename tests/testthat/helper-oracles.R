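# Independent brute-force oracles, deliberately naive: plain loops and
# base-R interval arithmetic, no GenomicRanges.

# overlap length of 1-based inclusive intervals
.ov <- function(a1, a2, b1, b2) max(0, min(a2, b2) - max(a1, b1) + 1)

# flatten a TranscriptSet into a plain data.frame of exons
flatExons <- function(ts) {
  ex <- exonRanges(ts)
  do.call(rbind, lapply(seq_along(ex), function(k) {
    g <- ex[[k]]
    data.frame(tx = names(ex)[k], chrom = as.character(seqnames(g)),
               start = start(g), end = end(g),
               strand = as.character(strand(g)))
  }))
}

# per-transcript span table
spanTable <- function(ts) {
  fe <- flatExons(ts)
  do.call(rbind, lapply(split(fe, fe$tx), function(d)
    data.frame(tx = d$tx[1], chrom = d$chrom[1], start = min(d$start),
               end = max(d$end), strand = d$strand[1])))
}

# all-pairs interval-scan class codes, following the written definitions
bruteClassCodes <- function(candidates, ref) {
  cex <- flatExons(candidates)
  rex <- flatExons(ref)
  rsp <- spanTable(ref)
  rsp$gene <- geneIds(ref)[match(rsp$tx, txIds(ref))]
  # gene loci = union span per gene
  gl <- do.call(rbind, lapply(split(rsp, rsp$gene), function(d)
    data.frame(chrom = d$chrom[1], start = min(d$start), end = max(d$end),
               strand = d$strand[1])))
  # introns of every reference transcript
  rin <- do.call(rbind, lapply(split(rex, rex$tx), function(d) {
    d <- d[order(d$start), ]
    if (nrow(d) < 2) return(NULL)
    data.frame(chrom = d$chrom[1], start = d$end[-nrow(d)] + 1,
               end = d$start[-1] - 1)
  }))
  vapply(txIds(candidates), function(id) {
    ce <- cex[cex$tx == id, ]
    cs <- ce$strand[1]
    span <- c(min(ce$start), max(ce$end))
    sense <- FALSE; anti <- FALSE
    for (i in seq_len(nrow(ce))) for (j in seq_len(nrow(rex))) {
      if (ce$chrom[i] != rex$chrom[j]) next
      if (.ov(ce$start[i], ce$end[i], rex$start[j], rex$end[j]) > 0) {
        if (cs == "*" || cs == rex$strand[j]) sense <- TRUE else anti <- TRUE
      }
    }
    if (sense) return("other")
    if (anti) return("x")
    if (!is.null(rin)) for (j in seq_len(nrow(rin)))
      if (ce$chrom[1] == rin$chrom[j] && span[1] >= rin$start[j] &&
          span[2] <= rin$end[j]) return("i")
    for (j in seq_len(nrow(gl)))
      if (ce$chrom[1] == gl$chrom[j] &&
          .ov(span[1], span[2], gl$start[j], gl$end[j]) > 0) return("other")
    "u"
  }, character(1))
}

# direct re-application of the five written lncRNA criteria
bruteFilter <- function(candidates, scores, maxfpkm) {
  ids <- txIds(candidates)
  sc <- scores[match(ids, scores$id), ]
  len <- txLengths(candidates)
  nex <- exonCounts(candidates)
  str <- txStrand(candidates)
  ok <- classCode(candidates) %in% c("u", "x", "i") &
    len > 200 &
    sc$cpc_score < 0 &
    !sc$pfam_hit &
    str != "*" &
    ifelse(nex >= 2, maxfpkm[ids] >= 0.5, maxfpkm[ids] >= 2)
  ids[ok]
}

# textbook Pearson correlation
brutePearson <- function(a, b) {
  n <- length(a)
  sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
}

# all-pairs correlation scan for the network oracle
bruteNetwork <- function(L, M, thr = 0.95) {
  out <- NULL
  for (i in rownames(L)) for (j in rownames(M)) {
    if (sd(L[i, ]) == 0 || sd(M[j, ]) == 0) next
    r <- brutePearson(L[i, ], M[j, ])
    if (abs(r) > thr)
      out <- rbind(out, data.frame(lncrna = i, mrna = j, r = r))
  }
  out
}

# double loop over transcript pairs x miRNAs for the ceRNA oracle
bruteSharedPairs <- function(bindings, include_mimic_mimic = FALSE) {
  txs <- sort(unique(bindings$transcript))
  out <- NULL
  for (i in seq_along(txs)) for (j in seq_len(i - 1L)) {
    a <- txs[j]; b <- txs[i]
    shared <- character(); links <- character()
    for (m in unique(bindings$mirna)) {
      am <- bindings$mode[bindings$mirna == m & bindings$transcript == a]
      bm <- bindings$mode[bindings$mirna == m & bindings$transcript == b]
      if (!length(am) || !length(bm)) next
      shared <- c(shared, m)
      links <- c(links,
                 if ("perfect" %in% am && "perfect" %in% bm) "tt"
                 else if ("perfect" %in% am || "perfect" %in% bm) "tm"
                 else "mm")
    }
    if (!length(shared)) next
    type <- if ("tt" %in% links) "target-target"
            else if ("tm" %in% links) "target-mimic" else "mimic-mimic"
    if (type == "mimic-mimic" && !include_mimic_mimic) next
    out <- rbind(out, data.frame(a = a, b = b, type = type,
                                 shared = paste(sort(shared),
                                                collapse = ";")))
  }
  out
}

# random binding table generator for property tests
randomBindings <- function(n_records, n_mirnas = 12, n_tx = 15) {
  repeat {
    d <- unique(data.frame(
      mirna = sprintf("m%02d", sample.int(n_mirnas, n_records, TRUE)),
      transcript = sprintf("t%02d", sample.int(n_tx, n_records, TRUE)),
      mode = sample(c("perfect", "mimic"), n_records, TRUE)))
    if (nrow(d) > 0) return(d)
  }
}

# hand-built two-gene reference on one chromosome:
#   gA: + strand, exons [1001,1200], [1501,1800], [2601,2900] (introns
#       [1201,1500], [1801,2600]); gB: - strand, exons [9001,9400],
#       [9901,10200]
tinyRef <- function() {
  grl <- GRangesList(
    gA.1 = GRanges("chr1",
                   IRanges(c(1001, 1501, 2601), c(1200, 1800, 2900)), "+"),
    gB.1 = GRanges("chr1", IRanges(c(9001, 9901), c(9400, 10200)), "-"))
  TranscriptSet(grl, geneId = c("gA", "gB"), biotype = "coding")
}
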