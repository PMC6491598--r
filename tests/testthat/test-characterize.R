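test_that("featureSummary computes per-class statistics", {
  grl <- GRangesList(
    a = GRanges("chr1", IRanges(1000, 1099), "+"),                      # 1 exon
    b = GRanges("chr1", IRanges(c(2000, 2500, 3000),
                                c(2136, 2699, 3099)), "+"))             # 3 exons
  ts <- TranscriptSet(grl, geneId = c("ga", "gb"), biotype = "lincRNA")
  fs <- featureSummary(ts)
  expect_equal(fs$mean_exons, 2)
  expect_equal(fs$fraction_spliced, 0.5)
  # exon lengths are 100, 137, 200, 100 -> median of (100,137,200) subset:
  expect_equal(stats::median(c(100, 137, 200)), 137)
  expect_true(is.na(featureSummary(ts)$median_fpkm))
  # empty classes are absent, not zero rows
  expect_false("lncNAT" %in% fs$class)
})

test_that("featureSummary equals brute-force recomputation on simulated data", {
  cfg <- simulationConfig(seed = 13)
  sim <- simulateCamLncData(cfg)
  cand <- assignClassCodes(sim$candidates, sim$ref)
  res <- filterLncRNA(cand, sim$scores,
                      SummarizedExperiment::cbind(sim$diel$green,
                                                  sim$diel$white))
  acc <- classifyBiotype(res$accepted, sim$ref)
  all_tx <- combineTranscriptSets(acc, sim$ref)
  fs <- featureSummary(all_tx)
  for (cl in fs$class) {
    sub <- all_tx[txBiotype(all_tx) == cl]
    fe <- flatExons(sub)
    expect_equal(fs$n[fs$class == cl], length(sub))
    expect_equal(fs$mean_exons[fs$class == cl],
                 mean(table(fe$tx)[txIds(sub)]))
    expect_equal(fs$median_exon_length[fs$class == cl],
                 stats::median(fe$end - fe$start + 1))
    lens <- vapply(split(fe, fe$tx), function(d)
      sum(d$end - d$start + 1), numeric(1))
    expect_equal(fs$median_tx_length[fs$class == cl],
                 stats::median(unname(lens)))
  }
})

test_that("antisense overlap fraction matches per-base counting", {
  ref <- tinyRef()   # gA spans [1001, 2900] on +
  grl <- GRangesList(
    inside  = GRanges("chr1", IRanges(1200, 1599), "-"),  # fully inside gA span
    partial = GRanges("chr1", IRanges(2801, 3200), "-"))  # 100 of 400 nt inside
  nat <- TranscriptSet(grl, geneId = c("n1", "n2"), biotype = "lncNAT")
  f <- antisenseOverlapFraction(nat, ref)
  expect_equal(unname(f["inside"]), 1.0)
  expect_equal(unname(f["partial"]), 0.25)

  # per-base oracle on a multi-exon lncNAT
  grl2 <- GRangesList(m = GRanges("chr1",
                                  IRanges(c(2700, 3000), c(2950, 3199)), "-"))
  nat2 <- TranscriptSet(grl2, geneId = "n3", biotype = "lncNAT")
  bases <- c(2700:2950, 3000:3199)
  frac <- mean(bases >= 1001 & bases <= 2900)   # gA locus, opposite strand
  expect_equal(unname(antisenseOverlapFraction(nat2, ref)["m"]), frac)

  # zero overlap violates the lncNAT precondition
  grl3 <- GRangesList(z = GRanges("chr1", IRanges(50000, 50400), "-"))
  expect_error(antisenseOverlapFraction(
    TranscriptSet(grl3, geneId = "n4", biotype = "lncNAT"), ref),
    "no antisense overlap")
})

test_that("locus distances use the intervening-base convention", {
  ref <- TranscriptSet(GRangesList(
    g1.1 = GRanges("chr1", IRanges(3000, 4000), "+"),
    g2.1 = GRanges("chr1", IRanges(8000, 9000), "-")),
    geneId = c("g1", "g2"), biotype = "coding")
  lnc <- TranscriptSet(GRangesList(
    near = GRanges("chr1", IRanges(1000, 2000), "+"),
    over = GRanges("chr1", IRanges(3500, 3600), "-")),
    geneId = c("l1", "l2"), biotype = "lincRNA")
  d <- locusDistances(lnc, ref)
  expect_equal(unname(d$lnc_to_gene["l1"]), 999)   # 3000 - 2000 - 1
  expect_equal(unname(d$lnc_to_gene["l2"]), 0)     # overlapping
  expect_equal(d$gene_to_gene, 8000 - 4000 - 1)
})

test_that("locus distances agree with an all-pairs scan and are strand-flip invariant", {
  cfg <- simulationConfig(seed = 29, n_coding_genes = 30, n_lincRNA = 10,
                          n_lncNAT = 5, n_intronic = 3, n_sense_overlap = 2,
                          n_rejected_by = c(short = 1, cpc = 1, pfam = 1,
                                            unstranded = 1, low_fpkm = 1),
                          n_cycling = c(both = 2, green_only = 2,
                                        white_only = 2),
                          n_cycling_neg = c(flat = 1, low_amplitude = 1,
                                            low_fold_change = 1),
                          triangles = list(list(focal = "PPCK.1",
                                                n_mirnas = 2, n_decoys = 3)))
  ann <- simulateAnnotation(cfg)
  lnc <- ann$candidates[sim_ids <- ann$truth$id[ann$truth$failure == "none"]]
  d <- locusDistances(lnc, ann$ref)

  # brute force: nearest gene per lncRNA gene (gene = transcript here)
  gsp <- spanTable(ann$ref)
  lsp <- spanTable(lnc)
  for (k in seq_len(nrow(lsp))) {
    ds <- vapply(seq_len(nrow(gsp)), function(j) {
      if (gsp$chrom[j] != lsp$chrom[k]) return(Inf)
      if (.ov(lsp$start[k], lsp$end[k], gsp$start[j], gsp$end[j]) > 0)
        return(0)
      if (gsp$start[j] > lsp$end[k]) gsp$start[j] - lsp$end[k] - 1
      else lsp$start[k] - gsp$end[j] - 1
    }, numeric(1))
    gene <- geneIds(lnc)[match(lsp$tx[k], txIds(lnc))]
    expect_equal(unname(d$lnc_to_gene[gene]), min(ds))
  }
  # gene-gene gaps per chromosome
  gg <- unlist(lapply(split(gsp, gsp$chrom), function(s) {
    s <- s[order(s$start), ]
    if (nrow(s) < 2) return(numeric(0))
    pmax(0, s$start[-1] - s$end[-nrow(s)] - 1)
  }), use.names = FALSE)
  expect_equal(sort(d$gene_to_gene), sort(gg))

  # intron lengths
  fe <- flatExons(ann$ref)
  introns <- unlist(lapply(split(fe, fe$tx), function(s) {
    s <- s[order(s$start), ]
    if (nrow(s) < 2) return(numeric(0))
    s$start[-1] - s$end[-nrow(s)] - 1
  }), use.names = FALSE)
  expect_equal(sort(d$intron_lengths), sort(introns))

  # flipping every strand leaves nearest-gene distances unchanged
  flip <- function(ts) {
    ex <- exonRanges(ts)
    flipped <- lapply(ex, function(g) {
      strand(g) <- ifelse(as.character(strand(g)) == "+", "-", "+")
      g
    })
    TranscriptSet(GRangesList(flipped), geneId = geneIds(ts),
                  classCode = classCode(ts), biotype = txBiotype(ts))
  }
  d2 <- locusDistances(flip(lnc), flip(ann$ref))
  expect_equal(d2$lnc_to_gene, d$lnc_to_gene)
})

test_that("KS comparison matches a direct ECDF computation", {
  expect_equal(compareExpressionDistributions(1:50, 1:50)$statistic, 0)
  a <- seq(0, 0.1, length.out = 50)
  b <- seq(10, 10.1, length.out = 50)
  expect_equal(compareExpressionDistributions(a, b)$statistic, 1)
  expect_error(compareExpressionDistributions(numeric(0), 1:3), "non-empty")

  set.seed(101)
  x <- rlnorm(100); y <- rlnorm(100)
  got <- compareExpressionDistributions(x, y)$statistic
  grid <- sort(c(x, y))
  manual <- max(abs(ecdf(x)(grid) - ecdf(y)(grid)))
  expect_equal(got, manual)
})
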