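#' Assemble a pipeline run configuration
#'
#' Collects input paths and per-stage parameters for [runPipeline()]. The
#' same structure round-trips through YAML via [readPipelineConfig()], and
#' every default is echoed into the run report for reproducibility.
#'
#' @param ref,candidates Annotation paths (GFF3/GTF).
#' @param scores CPC/Pfam score TSV.
#' @param tissues,tissues_samples Tissue expression TSV and sample sheet.
#' @param diel_green,diel_green_samples,diel_white,diel_white_samples Diel
#'   expression TSVs and sample sheets for the two leaf tissues.
#' @param bindings miRNA binding TSV.
#' @param focal Character vector of focal transcript ids for the ceRNA
#'   query.
#' @param out_dir Output directory.
#' @param seed Integer seed (governs the cycling permutations).
#' @param identification,specificity,cycling Per-stage parameter lists (see
#'   [identificationConfig()], [specificityConfig()], [cyclingConfig()]).
#' @param r_threshold Co-expression correlation threshold.
#' @return A named list of class \code{"camlnc_config"}.
#' @export
pipelineConfig <- function(ref, candidates, scores,
                           tissues, tissues_samples,
                           diel_green, diel_green_samples,
                           diel_white, diel_white_samples,
                           bindings, focal = character(),
                           out_dir = ".", seed = 1,
                           identification = identificationConfig(),
                           specificity = specificityConfig(),
                           cycling = cyclingConfig(seed = seed),
                           r_threshold = 0.95) {
  cfg <- as.list(environment())
  class(cfg) <- "camlnc_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Paths in the file are interpreted relative to the file's directory.
#'
#' @param path YAML file with the [pipelineConfig()] fields.
#' @return A \code{"camlnc_config"} list.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  pathify <- function(f) if (!is.null(y[[f]]))
    file.path(base, y[[f]]) else NULL
  args <- y
  for (f in c("ref", "candidates", "scores", "tissues", "tissues_samples",
              "diel_green", "diel_green_samples", "diel_white",
              "diel_white_samples", "bindings"))
    args[[f]] <- pathify(f)
  for (f in c("identification", "specificity", "cycling"))
    if (!is.null(args[[f]]))
      args[[f]] <- do.call(switch(f, identification = identificationConfig,
                                  specificity = specificityConfig,
                                  cycling = cyclingConfig), args[[f]])
  do.call(pipelineConfig, args)
}

.stopIfMissing <- function(cfg) {
  need <- c("ref", "candidates", "scores", "tissues", "tissues_samples",
            "diel_green", "diel_green_samples", "diel_white",
            "diel_white_samples", "bindings")
  for (f in need) {
    if (is.null(cfg[[f]]))
      stop("config field missing: ", f)
    if (!file.exists(cfg[[f]]))
      stop("config field '", f, "' points to a missing file: ", cfg[[f]])
  }
}

#' Run the full lncRNA analysis pipeline
#'
#' Executes the stages in dependency order: identification (class codes,
#' five-criterion filter, biotype classification), genomic-feature
#' characterization, tissue-specificity scoring, co-expression network
#' construction over the combined two-tissue diel conditions, ceRNA pair
#' construction with focal-gene queries, and diel-cycling detection with
#' two-tissue overlap classes. Writes per-stage TSVs plus a deterministic
#' JSON run report (counts, parameters, seed; no timestamps, so identical
#' configurations give byte-identical reports).
#'
#' @param cfg A \code{"camlnc_config"} from [pipelineConfig()] or
#'   [readPipelineConfig()].
#' @return Invisibly, the report as a list. Side effect: files under
#'   \code{cfg$out_dir}.
#' @export
runPipeline <- function(cfg) {
  .stopIfMissing(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(cfg$out_dir, f)
  report <- list(seed = cfg$seed,
                 parameters = list(
                   identification = cfg$identification,
                   specificity = cfg$specificity,
                   cycling = cfg$cycling,
                   r_threshold = cfg$r_threshold),
                 stages = list())

  # -- identify ---------------------------------------------------------
  ref <- readAnnotation(cfg$ref, biotype = "coding")
  cand <- readAnnotation(cfg$candidates, biotype = "candidate")
  scores <- read.delim(cfg$scores, stringsAsFactors = FALSE)
  green <- readExpression(cfg$diel_green, cfg$diel_green_samples)
  white <- readExpression(cfg$diel_white, cfg$diel_white_samples)
  diel_all <- SummarizedExperiment::cbind(green, white)

  cand <- assignClassCodes(cand, ref)
  filt <- filterLncRNA(cand, scores, diel_all, cfg$identification)
  accepted <- classifyBiotype(filt$accepted, ref)
  writeAnnotationGTF(accepted, p("accepted.gtf"))
  if (length(filt$low_confidence))
    writeAnnotationGTF(filt$low_confidence, p("low_confidence.gtf"))
  funnel_out <- filt$funnel
  funnel_out$rejected <- vapply(funnel_out$rejected, paste, character(1),
                                collapse = ";")
  write.table(funnel_out, p("funnel.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  report$stages$identify <- list(
    candidates = length(cand),
    accepted = length(accepted),
    low_confidence = length(filt$low_confidence),
    lincRNA = sum(txBiotype(accepted) == "lincRNA"),
    lncNAT = sum(txBiotype(accepted) == "lncNAT"),
    funnel = funnel_out[, c("step", "n_in", "n_out")])

  # -- characterize -----------------------------------------------------
  both <- combineTranscriptSets(accepted, ref)
  diel_cond <- collapseReplicates(diel_all)
  fs <- featureSummary(both, diel_cond)
  write.table(fs[, setdiff(colnames(fs), "exon_count_table")],
              p("feature_summary.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  dist <- locusDistances(accepted, ref)
  report$stages$characterize <- list(
    classes = fs$class, medians = as.list(dist$medians))

  # -- tissue specificity ----------------------------------------------
  tis <- readExpression(cfg$tissues, cfg$tissues_samples)
  spec <- callSpecificity(tis, cfg$specificity)
  write.table(spec, p("specificity.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  lnc_spec <- spec[spec$transcript %in% txIds(accepted), ]
  report$stages$tissue_specificity <- list(
    scored = nrow(spec),
    tissue_specific = sum(spec$is_tissue_specific),
    lnc_tissue_specific = sum(lnc_spec$is_tissue_specific),
    uniquely_expressed = sum(spec$is_uniquely_expressed))

  # -- coexpression -----------------------------------------------------
  m <- assay(diel_cond, "fpkm")
  net <- buildCoexpressionNetwork(m[txIds(accepted), , drop = FALSE],
                                  m[txIds(ref), , drop = FALSE],
                                  cfg$r_threshold)
  write.table(net, p("coexpression_edges.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeCoexpressionGraphML(net, p("coexpression.graphml"))
  report$stages$coexpression <- list(
    edges = nrow(net),
    positive = sum(net$sign == "positive"),
    negative = sum(net$sign == "negative"),
    skipped_pairs = attr(net, "n_skipped_pairs"))

  # -- ceRNA ------------------------------------------------------------
  bindings <- readBindingTable(cfg$bindings)
  pairs <- sharedMirnaPairs(bindings)
  writeCernaPairs(pairs, p("cerna_pairs.tsv"))
  classes <- c(stats::setNames(txBiotype(accepted), txIds(accepted)),
               stats::setNames(rep("mRNA", length(ref)), txIds(ref)))
  txs <- unique(c(pairs$transcript_a, pairs$transcript_b))
  classes[setdiff(txs, names(classes))] <- "mRNA"
  writeCernaGraphML(pairs, classes, p("cerna.graphml"))
  focal_res <- lapply(cfg$focal, function(f)
    if (f %in% bindings$transcript) {
      fc <- focalCerna(bindings, f)
      list(partners = length(fc$partners),
           competed_mirnas = length(fc$competed_mirnas))
    } else list(partners = 0, competed_mirnas = 0))
  names(focal_res) <- cfg$focal
  report$stages$cerna <- list(
    pairs = nrow(pairs),
    target_target = sum(pairs$pair_type == "target-target"),
    target_mimic = sum(pairs$pair_type == "target-mimic"),
    focal = focal_res)

  # -- diel cycling -----------------------------------------------------
  grid <- sort(unique(colData(green)$time_hour))
  lib <- buildModelLibrary(grid)
  lnc_green <- green[txIds(accepted), ]
  lnc_white <- white[txIds(accepted), ]
  calls_g <- scoreCycling(lnc_green, lib, cfg$cycling, tissue = "green")
  calls_w <- scoreCycling(lnc_white, lib, cfg$cycling, tissue = "white")
  write.table(calls_g, p("cycling_green.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(calls_w, p("cycling_white.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  ov <- classifyOverlap(calls_g, calls_w)
  write.table(ov, p("cycling_overlap.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  tab <- table(factor(ov$class,
                      levels = c("both", "green-only", "white-only", "none")))
  report$stages$cycling <- list(
    universe = nrow(ov),
    cycling_any = sum(ov$class != "none"),
    both = unname(tab["both"]), green_only = unname(tab["green-only"]),
    white_only = unname(tab["white-only"]), none = unname(tab["none"]))

  jsonlite::write_json(report, p("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "columns")
  invisible(report)
}

#' One-command synthetic demonstration
#'
#' Simulates a complete synthetic study under the given seed, writes the
#' fixtures to \code{<out_dir>/fixtures/}, runs the full pipeline on them
#' into \code{<out_dir>/results/}, and returns the run report. Two calls
#' with the same seed produce byte-identical reports.
#'
#' @param out_dir Working directory (created if needed).
#' @param seed Integer seed.
#' @param sim_config Optional [simulationConfig()] override (its seed
#'   wins).
#' @return Invisibly, a list with \code{report}, \code{report_path},
#'   \code{sim} and the fixture/result directories.
#' @export
runDemo <- function(out_dir, seed = 1, sim_config = NULL) {
  cfg <- if (is.null(sim_config)) simulationConfig(seed = seed)
         else sim_config
  sim <- simulateCamLncData(cfg)
  fixdir <- file.path(out_dir, "fixtures")
  resdir <- file.path(out_dir, "results")
  files <- writeFixtures(sim, fixdir)
  pcfg <- pipelineConfig(
    ref = files[["ref.gff3"]], candidates = files[["candidates.gtf"]],
    scores = files[["scores.tsv"]], tissues = files[["tissues.tsv"]],
    tissues_samples = files[["tissues_samples.tsv"]],
    diel_green = files[["diel_green.tsv"]],
    diel_green_samples = files[["diel_green_samples.tsv"]],
    diel_white = files[["diel_white.tsv"]],
    diel_white_samples = files[["diel_white_samples.tsv"]],
    bindings = files[["bindings.tsv"]],
    focal = vapply(cfg$triangles, `[[`, character(1), "focal"),
    out_dir = resdir, seed = cfg$seed)
  report <- runPipeline(pcfg)
  invisible(list(report = report,
                 report_path = file.path(resdir, "report.json"),
                 sim = sim, fixtures = fixdir, results = resdir))
}
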