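# candidates with known relationships to the tinyRef() two-gene annotation
.tinyCandidates <- function() {
  grl <- GRangesList(
    far      = GRanges("chr1", IRanges(20000, 20400), "+"),   # intergenic
    anti     = GRanges("chr1", IRanges(1100, 1400), "-"),     # x: hits gA exon 1
    intronic = GRanges("chr1", IRanges(1900, 2400), "+"),     # i: inside gA intron 2
    sense    = GRanges("chr1", IRanges(1100, 1400), "+"),     # sense overlap
    anti_in  = GRanges("chr1", IRanges(1900, 2400), "-"))     # i, antisense host
  TranscriptSet(grl, geneId = paste0("X", 1:5), biotype = "candidate")
}

test_that("class codes follow the u/x/i/other definitions", {
  cand <- assignClassCodes(.tinyCandidates(), tinyRef())
  cc <- setNames(classCode(cand), txIds(cand))
  expect_equal(unname(cc["far"]), "u")
  expect_equal(unname(cc["anti"]), "x")
  expect_equal(unname(cc["intronic"]), "i")
  expect_equal(unname(cc["sense"]), "other")
  expect_equal(unname(cc["anti_in"]), "i")
})

test_that("candidate on a chromosome absent from the reference errors", {
  bad <- TranscriptSet(GRangesList(
    t1 = GRanges("chrZ", IRanges(1, 100), "+")), geneId = "g")
  expect_error(assignClassCodes(bad, tinyRef()), "absent from reference")
})

test_that("class codes match the brute-force all-pairs interval oracle", {
  cfg <- simulationConfig(seed = 19, n_coding_genes = 40, n_lincRNA = 12,
                          n_lncNAT = 8, n_intronic = 6, n_sense_overlap = 4,
                          n_rejected_by = c(short = 3, cpc = 3, pfam = 3,
                                            unstranded = 3, low_fpkm = 3),
                          n_cycling = c(both = 2, green_only = 2,
                                        white_only = 2),
                          n_cycling_neg = c(flat = 1, low_amplitude = 1,
                                            low_fold_change = 1),
                          triangles = list(list(focal = "PPCK.1",
                                                n_mirnas = 2, n_decoys = 3)))
  ann <- simulateAnnotation(cfg)
  got <- classCode(assignClassCodes(ann$candidates, ann$ref))
  oracle <- bruteClassCodes(ann$candidates, ann$ref)
  expect_equal(unname(got), unname(oracle[txIds(ann$candidates)]))
  # exactly one code per candidate, all defined
  expect_true(all(got %in% c("u", "x", "i", "other")))
})

test_that("the filter funnel applies the five criteria in order", {
  ref <- tinyRef()
  grl <- GRangesList(
    ok2ex  = GRanges("chr1", IRanges(c(20000, 20500), c(20150, 20700)), "+"),
    short1 = GRanges("chr1", IRanges(30000, 30149), "+"),          # 150 nt
    mono   = GRanges("chr1", IRanges(40000, 40400), "+"),          # 1 exon
    cpc0   = GRanges("chr1", IRanges(50000, 50400), "+"))
  cand <- TranscriptSet(grl, geneId = paste0("X", 1:4),
                        biotype = "candidate")
  cand <- assignClassCodes(cand, ref)
  scores <- data.frame(id = txIds(cand),
                       cpc_score = c(-1.2, -2, -1, 0),
                       pfam_hit = FALSE)
  m <- matrix(c(0.7, 0.7,    # ok2ex: multi-exon, max 0.7 >= 0.5 -> pass
                5,   5,      # short1: expression fine, fails length only
                1.5, 1.2,    # mono: single exon, max 1.5 < 2 -> low conf
                6,   6),     # cpc0: fails the strict CPC < 0 rule
              4, 2, byrow = TRUE,
              dimnames = list(txIds(cand), c("s1", "s2")))
  expr <- fpkmExperiment(m, tissue = "leaf")
  res <- filterLncRNA(cand, scores, expr)

  expect_equal(txIds(res$accepted), "ok2ex")
  expect_equal(txIds(res$low_confidence), "mono")   # fails expression only
  expect_true("short1" %in% res$funnel$rejected[[
    which(res$funnel$step == "length")]])
  expect_true("cpc0" %in% res$funnel$rejected[[
    which(res$funnel$step == "cpc")]])              # CPC score 0 is rejected
  expect_true(all(diff(res$funnel$n_out) <= 0 |
                  res$funnel$n_in[-1] == res$funnel$n_out[-nrow(res$funnel)]))
  # chaining: survivors of step k enter step k+1
  expect_equal(res$funnel$n_in[-1], res$funnel$n_out[-nrow(res$funnel)])
})

test_that("a missing score row errors naming the transcript", {
  cand <- assignClassCodes(.tinyCandidates(), tinyRef())
  scores <- data.frame(id = txIds(cand)[-1], cpc_score = -1,
                       pfam_hit = FALSE)
  m <- matrix(5, length(cand), 2,
              dimnames = list(txIds(cand), c("a", "b")))
  expect_error(filterLncRNA(cand, scores, fpkmExperiment(m, "leaf")),
               "far")
})

test_that("accepted set equals brute-force re-application of the criteria and the funnel partitions candidates", {
  cfg <- simulationConfig(seed = 23)
  sim <- simulateCamLncData(cfg)
  cand <- assignClassCodes(sim$candidates, sim$ref)
  expr <- SummarizedExperiment::cbind(sim$diel$green, sim$diel$white)
  res <- filterLncRNA(cand, sim$scores, expr)

  cond <- collapseReplicates(expr)
  maxfpkm <- apply(SummarizedExperiment::assay(cond), 1, max)
  expect_setequal(txIds(res$accepted), bruteFilter(cand, sim$scores, maxfpkm))

  # funnel monotone, and rejected ids partition the complement
  expect_true(all(diff(res$funnel$n_in) <= 0))
  rej <- unlist(res$funnel$rejected)
  expect_equal(anyDuplicated(rej), 0L)
  expect_setequal(c(rej, txIds(res$accepted)), txIds(cand))
  # low-confidence transcripts fail only strand or expression
  expect_true(all(txIds(res$low_confidence) %in% unlist(
    res$funnel$rejected[res$funnel$step %in% c("strand", "expression")])))
})

test_that("biotype classification partitions accepted transcripts and recovers planted labels", {
  cand <- assignClassCodes(.tinyCandidates(), tinyRef())
  keep <- cand[txIds(cand) %in% c("far", "anti", "intronic", "anti_in")]
  out <- classifyBiotype(keep, tinyRef())
  bt <- setNames(txBiotype(out), txIds(out))
  expect_equal(unname(bt["far"]), "lincRNA")        # 'u' is definitionally lincRNA
  expect_equal(unname(bt["anti"]), "lncNAT")
  expect_equal(unname(bt["intronic"]), "lincRNA")   # sense-intronic
  expect_equal(unname(bt["anti_in"]), "lncNAT")     # antisense-intronic
  expect_true(all(txBiotype(out) %in% c("lincRNA", "lncNAT")))

  cfg <- simulationConfig(seed = 31)
  sim <- simulateCamLncData(cfg)
  cand <- assignClassCodes(sim$candidates, sim$ref)
  res <- filterLncRNA(cand, sim$scores,
                      SummarizedExperiment::cbind(sim$diel$green,
                                                  sim$diel$white))
  acc <- classifyBiotype(res$accepted, sim$ref)
  tt <- sim$truth$transcripts
  expect_equal(unname(txBiotype(acc)),
               tt$biotype[match(txIds(acc), tt$id)])
})
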