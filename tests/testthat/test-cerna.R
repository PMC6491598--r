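test_that("shared-miRNA pairing follows the written examples", {
  b <- data.frame(mirna = c("m1", "m1", "m2"),
                  transcript = c("A", "B", "C"),
                  mode = "perfect")
  p <- sharedMirnaPairs(b)
  expect_equal(nrow(p), 1)
  expect_equal(p$transcript_a, "A")
  expect_equal(p$transcript_b, "B")
  expect_equal(p$pair_type, "target-target")
  expect_equal(p$shared_mirnas[[1]], "m1")

  # no sharing -> empty
  b2 <- data.frame(mirna = c("m1", "m2"), transcript = c("A", "B"),
                   mode = "perfect")
  expect_equal(nrow(sharedMirnaPairs(b2)), 0)
  expect_equal(nrow(sharedMirnaPairs(b2[0, ])), 0)
})

test_that("a PPCK-style triangle yields five target-mimic focal partners", {
  b <- rbind(
    data.frame(mirna = c("m1", "m2"), transcript = "PPCK", mode = "perfect"),
    data.frame(mirna = c("m1", "m2", "m1", "m2", "m1"),
               transcript = c("lnc1", "lnc2", "lnc3", "lnc4", "lnc5"),
               mode = "mimic"))
  fc <- focalCerna(b, "PPCK")
  expect_setequal(fc$partners, paste0("lnc", 1:5))
  expect_setequal(fc$competed_mirnas, c("m1", "m2"))
  expect_true(all(fc$pairs$pair_type == "target-mimic"))
  expect_error(focalCerna(b, "missing"), "not present")
  # a focal transcript sharing nothing has no partners
  b3 <- rbind(b, data.frame(mirna = "m9", transcript = "solo",
                            mode = "perfect"))
  expect_length(focalCerna(b3, "solo")$partners, 0)
})

test_that("pair typing uses strongest shared evidence; mimic-mimic pairs are excluded by default", {
  b <- data.frame(
    mirna      = c("m1", "m1", "m2", "m2", "m3", "m3"),
    transcript = c("A",  "B",  "A",  "B",  "C",  "D"),
    mode       = c("perfect", "mimic", "perfect", "perfect",
                   "mimic", "mimic"))
  p <- sharedMirnaPairs(b)
  ab <- p[p$transcript_a == "A" & p$transcript_b == "B", ]
  expect_equal(ab$pair_type, "target-target")    # m2 link is perfect-perfect
  expect_equal(ab$shared_mirnas[[1]], c("m1", "m2"))
  expect_false(any(p$transcript_a == "C"))       # mimic-mimic dropped
  p2 <- sharedMirnaPairs(b, include_mimic_mimic = TRUE)
  cd <- p2[p2$transcript_a == "C", ]
  expect_equal(cd$pair_type, "mimic-mimic")
})

test_that("pairing equals the brute-force double loop and is monotone under added records", {
  set.seed(41)
  for (rep in 1:5) {
    b <- randomBindings(60)
    p <- sharedMirnaPairs(b)
    oracle <- bruteSharedPairs(b)
    if (is.null(oracle)) {
      expect_equal(nrow(p), 0)
      next
    }
    key <- function(a_, b_, t_, s_) sort(paste(a_, b_, t_, s_))
    expect_equal(
      key(p$transcript_a, p$transcript_b, p$pair_type,
          vapply(p$shared_mirnas, paste, character(1), collapse = ";")),
      key(oracle$a, oracle$b, oracle$type, oracle$shared))

    # adding one record never removes an existing pair
    extra <- data.frame(mirna = "mX", transcript = "tX", mode = "perfect")
    p3 <- sharedMirnaPairs(rbind(b, extra), include_mimic_mimic = TRUE)
    p2 <- sharedMirnaPairs(b, include_mimic_mimic = TRUE)
    old <- paste(p2$transcript_a, p2$transcript_b)
    expect_true(all(old %in% paste(p3$transcript_a, p3$transcript_b)))
  }
})

test_that("planted ceRNA triangles are recovered from simulated binding tables", {
  cfg <- simulationConfig(seed = 47)
  sim <- simulateCamLncData(cfg)
  fc <- focalCerna(sim$bindings$bindings, "PPCK.1")
  truth <- sim$truth$cerna
  planted <- truth$partner[truth$focal == "PPCK.1"]
  expect_setequal(fc$partners, planted)
  expect_length(fc$competed_mirnas, 2)
  # shared sets match the manifest exactly
  for (k in seq_len(nrow(fc$pairs))) {
    partner <- setdiff(c(fc$pairs$transcript_a[k], fc$pairs$transcript_b[k]),
                       "PPCK.1")
    expect_equal(paste(fc$pairs$shared_mirnas[[k]], collapse = ";"),
                 truth$shared_mirnas[truth$focal == "PPCK.1" &
                                     truth$partner == partner])
  }
  # zero triangles and no background sharing -> no pairs
  cfg0 <- simulationConfig(seed = 47, triangles = list(), n_tt_pairs = 0)
  sim0 <- simulateBindings(cfg0, paste0("l", 1:10), paste0("m", 1:10))
  expect_equal(nrow(sharedMirnaPairs(sim0$bindings,
                                     include_mimic_mimic = TRUE)), 0)
})

test_that("ceRNA GraphML export is tripartite and complete", {
  b <- rbind(
    data.frame(mirna = c("m1", "m2"), transcript = "PPCK", mode = "perfect"),
    data.frame(mirna = c("m1", "m2"), transcript = c("lnc1", "lnc2"),
               mode = "mimic"))
  p <- sharedMirnaPairs(b)
  classes <- c(PPCK = "mRNA", lnc1 = "lincRNA", lnc2 = "lncNAT")
  path <- tempfile(fileext = ".graphml")
  writeCernaGraphML(p, classes, path)
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns(doc)
  nodes <- xml2::xml_find_all(doc, "//d1:node", ns)
  expect_equal(length(nodes), 5)          # 3 transcripts + 2 miRNAs
  edges <- xml2::xml_find_all(doc, "//d1:edge", ns)
  # miRNA-transcript binding edges (m1-PPCK, m1-lnc1, m2-PPCK, m2-lnc2)
  # plus 2 ceRNA pair edges
  expect_equal(length(edges), 6)
  expect_error(writeCernaGraphML(p, classes[-1], path), "unclassified")

  # empty pair list gives a well-formed header-only file
  writeCernaGraphML(p[0, ], character(0), path)
  expect_silent(xml2::read_xml(path))
})
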