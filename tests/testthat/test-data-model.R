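test_that("GTF parsing groups and sorts exons per transcript", {
  gtf <- file.path(tempdir(), "tiny.gtf")
  writeLines(c(
    'chr1\ttest\texon\t500\t600\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\ttest\texon\t100\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";'),
    gtf)
  ts <- readAnnotation(gtf, biotype = "candidate")
  expect_equal(length(ts), 1L)
  expect_equal(unname(geneIds(ts)), "g1")
  ex <- exonRanges(ts)[["t1"]]
  expect_equal(start(ex), c(100, 500))   # out-of-order input comes back sorted
  expect_equal(unname(exonCounts(ts)), 2L)
  expect_equal(unname(txLengths(ts)), 101L + 101L)
})

test_that("annotation write-then-read round trip preserves the feature set", {
  cfg <- simulationConfig(seed = 11, n_coding_genes = 50, n_lincRNA = 15,
                          n_lncNAT = 8, n_intronic = 4, n_sense_overlap = 3,
                          n_rejected_by = c(short = 2, cpc = 2, pfam = 2,
                                            unstranded = 2, low_fpkm = 2),
                          n_cycling = c(both = 2, green_only = 2,
                                        white_only = 2),
                          n_cycling_neg = c(flat = 1, low_amplitude = 1,
                                            low_fold_change = 1),
                          triangles = list(list(focal = "PPCK.1",
                                                n_mirnas = 2, n_decoys = 3)))
  ann <- simulateAnnotation(cfg)
  for (obj in list(ann$ref, ann$candidates)) {
    path <- tempfile(fileext = ".gtf")
    writeAnnotationGTF(obj, path)
    back <- readAnnotation(path, biotype = "candidate")
    expect_setequal(txIds(back), txIds(obj))
    ord <- txIds(obj)
    expect_equal(unname(geneIds(back)[match(ord, txIds(back))]),
                 unname(geneIds(obj)))
    expect_equal(unname(txStrand(back)[ord]), unname(txStrand(obj)))
    for (id in ord) {
      a <- exonRanges(obj)[[id]]; b <- exonRanges(back)[[id]]
      expect_equal(start(b), start(a))
      expect_equal(end(b), end(a))
    }
  }
  # GFF3 route as well
  path <- tempfile(fileext = ".gff3")
  writeAnnotationGFF3(ann$ref, path)
  back <- readAnnotation(path)
  expect_setequal(txIds(back), txIds(ann$ref))
  expect_equal(unname(geneIds(back)[match(txIds(ann$ref), txIds(back))]),
               unname(geneIds(ann$ref)))
})

test_that("expression IO enforces numeric non-negative values", {
  m <- matrix(0, 3, 2, dimnames = list(paste0("t", 1:3), c("s1", "s2")))
  se <- fpkmExperiment(m, tissue = c("leaf", "root"))
  expect_equal(dim(se), c(3L, 2L))
  expect_true(all(SummarizedExperiment::assay(se) == 0))
  expect_error(fpkmExperiment(matrix(c(1, -1), 1, 2,
                                     dimnames = list("t", c("a", "b"))),
                              tissue = "x"),
               "non-negative")

  # a -1.0 cell in a file is rejected on read
  path <- tempfile(); sheet <- tempfile()
  writeLines(c("transcript\ts1\ts2", "t1\t0.5\t-1.0"), path)
  writeLines(c("sample\ttissue\ttime_hour\treplicate",
               "s1\tleaf\tNA\tNA", "s2\tleaf\tNA\tNA"), sheet)
  expect_error(readExpression(path, sheet), "non-negative")

  # sample absent from the sheet is a metadata error
  writeLines(c("transcript\ts1\ts2", "t1\t0.5\t1.0"), path)
  writeLines(c("sample\ttissue\ttime_hour\treplicate", "s1\tleaf\tNA\tNA"),
             sheet)
  expect_error(readExpression(path, sheet), "absent from sample sheet")
})

test_that("diel expression matrices round-trip through TSV", {
  cfg <- simulationConfig(seed = 5)
  sim <- simulateCamLncData(cfg)
  path <- tempfile(); sheet <- tempfile()
  writeExpression(sim$diel$green, path, sheet)
  back <- readExpression(path, sheet)
  expect_identical(SummarizedExperiment::assay(back),
                   SummarizedExperiment::assay(sim$diel$green))
  expect_equal(SummarizedExperiment::colData(back)$time_hour,
               SummarizedExperiment::colData(sim$diel$green)$time_hour)
})

test_that("collapseReplicates averages per condition", {
  m <- matrix(c(1, 2, 3), 1, 3,
              dimnames = list("t1", c("a_r1", "a_r2", "a_r3")))
  se <- fpkmExperiment(m, tissue = "leaf", time_hour = 4,
                       replicate = 1:3)
  out <- collapseReplicates(se)
  expect_equal(unname(SummarizedExperiment::assay(out)[1, 1]), 2)
  expect_equal(ncol(out), 1L)

  # single replicate is the identity on values
  se1 <- fpkmExperiment(matrix(7, 1, 1, dimnames = list("t1", "s")),
                        tissue = "leaf", time_hour = 2, replicate = 1)
  expect_equal(unname(SummarizedExperiment::assay(collapseReplicates(se1))[1, 1]), 7)
})

test_that("collapseReplicates matches brute-force means and commutes with row subsetting", {
  set.seed(42)
  m <- matrix(runif(60), 10, 6,
              dimnames = list(paste0("t", 1:10), paste0("s", 1:6)))
  se <- fpkmExperiment(m, tissue = rep(c("green", "white"), each = 3),
                       time_hour = 0, replicate = rep(1:3, 2))
  out <- SummarizedExperiment::assay(collapseReplicates(se))
  brute <- cbind(rowMeans(m[, 1:3]), rowMeans(m[, 4:6]))
  expect_equal(unname(out), unname(brute))

  sub <- collapseReplicates(se[c("t2", "t5"), ])
  full <- collapseReplicates(se)[c("t2", "t5"), ]
  expect_equal(SummarizedExperiment::assay(sub),
               SummarizedExperiment::assay(full))
})

test_that("coordinate conversion to half-open and back is the identity", {
  s <- c(1L, 100L, 2500L); e <- c(1L, 199L, 2600L)
  ho <- toHalfOpen(s, e)
  expect_equal(ho$end0 - ho$start0, e - s + 1)   # widths agree
  back <- fromHalfOpen(ho$start0, ho$end0)
  expect_identical(back$start, s)
  expect_identical(back$end, e)
})

test_that("TranscriptSet validity rejects malformed objects", {
  # exon beyond the declared chromosome length (GRanges itself also warns)
  gr <- suppressWarnings(
    GRangesList(t1 = GRanges("chr1", IRanges(900, 1100), "+",
                             seqinfo = Seqinfo("chr1", 1000))))
  expect_error(suppressWarnings(TranscriptSet(gr, geneId = "g")), "exceed")
  # overlapping exons within a transcript
  gr2 <- GRangesList(t1 = GRanges("chr1", IRanges(c(1, 50), c(100, 150)), "+"))
  expect_error(TranscriptSet(gr2, geneId = "g"), "non-overlapping")
  # unknown strand is only legal for candidate/rejected biotypes
  gr3 <- GRangesList(t1 = GRanges("chr1", IRanges(1, 100), "*"))
  expect_error(TranscriptSet(gr3, geneId = "g", biotype = "coding"),
               "unknown strand")
  expect_s4_class(TranscriptSet(gr3, geneId = "g", biotype = "candidate"),
                  "TranscriptSet")
})

test_that("binding table validation rejects bad modes and duplicates", {
  good <- data.frame(mirna = "m1", transcript = c("a", "b"),
                     mode = c("perfect", "mimic"))
  expect_silent(validateBindingTable(good))
  expect_error(validateBindingTable(transform(good, mode = "weak")),
               "perfect")
  expect_error(validateBindingTable(rbind(good, good[1, ])), "duplicate")
})
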