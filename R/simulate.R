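#' Simulation configuration with planted ground truth
#'
#' Describes a synthetic study emulating a CAM-leaf lncRNA survey: a
#' reference annotation of protein-coding genes, assembled candidate
#' transcripts with planted class codes and per-criterion filter failures,
#' four-tissue expression with planted tissue-specific rows, two-tissue
#' (green leaf tip, white leaf base) diel series on a 13-point 24-h grid
#' with planted cycling classes, and miRNA binding tables with planted
#' ceRNA triangles around two focal CAM genes (PEPC-like and PPCK-like).
#'
#' Planted filter failures violate exactly one criterion each, so a failure
#' at any funnel step is attributable. Planted positive cyclers use the
#' cosine, box and sawtooth shapes; amplitude and baseline ranges are chosen
#' so that amplitude (> 10 FPKM) and fold change (> 2) clear their
#' thresholds jointly, while the dedicated negative classes (flat,
#' low-amplitude, low-fold-change) each violate exactly one criterion.
#'
#' @param seed Integer RNG seed (mandatory; all randomness flows from it).
#' @param n_coding_genes Number of reference protein-coding genes.
#' @param n_lincRNA,n_lncNAT,n_intronic Planted intergenic ('u'), antisense
#'   exonic ('x') and intronic ('i') lncRNA candidates. Intronic candidates
#'   alternate sense/antisense relative to their host gene.
#' @param n_sense_overlap Planted sense-overlap candidates (class 'other',
#'   rejected at the class-code step).
#' @param n_rejected_by Named integer vector of per-criterion planted
#'   failures: \code{short}, \code{cpc}, \code{pfam}, \code{unstranded},
#'   \code{low_fpkm}.
#' @param tissues Tissue labels for the specificity matrix.
#' @param n_specific_per_tissue Planted tissue-specific rows per tissue.
#' @param diel_grid Clock hours of the diel sampling grid (13 points over
#'   24 h by default).
#' @param n_cycling Named vector: planted cyclers in \code{both},
#'   \code{green_only}, \code{white_only}.
#' @param n_cycling_neg Named vector of per-criterion cycling negatives:
#'   \code{flat}, \code{low_amplitude}, \code{low_fold_change}.
#' @param noise_sd Gaussian noise SD (FPKM) added per replicate; 0 gives
#'   exact planted-truth recovery.
#' @param n_replicates Biological replicates per diel sample (default 3).
#' @param triangles List of planted ceRNA triangles, each
#'   \code{list(focal=, n_mirnas=, n_decoys=)}.
#' @param n_background_mirnas Background miRNAs binding a single transcript
#'   each (they create no ceRNA pairs).
#' @param n_tt_pairs Planted target-target mRNA pairs.
#' @return A validated named list.
#' @export
simulationConfig <- function(seed,
                             n_coding_genes = 60,
                             n_lincRNA = 20,
                             n_lncNAT = 10,
                             n_intronic = 6,
                             n_sense_overlap = 5,
                             n_rejected_by = c(short = 5, cpc = 5, pfam = 5,
                                               unstranded = 5, low_fpkm = 6),
                             tissues = c("flower", "leaf", "root", "fruit"),
                             n_specific_per_tissue = 5,
                             diel_grid = c(0, 2, 4, 6, 8, 10, 12, 13, 15, 16,
                                           18, 20, 22),
                             n_cycling = c(both = 6, green_only = 6,
                                           white_only = 6),
                             n_cycling_neg = c(flat = 4, low_amplitude = 4,
                                               low_fold_change = 4),
                             noise_sd = 0,
                             n_replicates = 3,
                             triangles = list(
                               list(focal = "PPCK.1", n_mirnas = 2,
                                    n_decoys = 5),
                               list(focal = "PEPC.1", n_mirnas = 5,
                                    n_decoys = 10)),
                             n_background_mirnas = 30,
                             n_tt_pairs = 3) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- as.list(environment())
  counts <- c(n_coding_genes, n_lincRNA, n_lncNAT, n_intronic,
              n_sense_overlap, n_rejected_by, n_specific_per_tissue,
              n_cycling, n_cycling_neg, n_background_mirnas, n_tt_pairs)
  if (any(counts < 0)) stop("all counts must be >= 0")
  need <- c("short", "cpc", "pfam", "unstranded", "low_fpkm")
  if (!all(need %in% names(n_rejected_by)))
    stop("n_rejected_by needs entries: ", paste(need, collapse = ", "))
  n_u <- n_lincRNA + sum(n_rejected_by)
  if (n_coding_genes < n_u)
    stop("chromosome capacity insufficient: need >= ", n_u,
         " intergenic gaps but only ", n_coding_genes, " genes")
  if (n_coding_genes < n_lncNAT + n_intronic + n_sense_overlap)
    stop("chromosome capacity insufficient: too few host genes")
  n_lnc_acc <- n_lincRNA + n_lncNAT + n_intronic
  if (sum(n_cycling) + sum(n_cycling_neg) > n_lnc_acc)
    stop("more planted cycling transcripts than accepted lncRNAs")
  if (sum(vapply(triangles, `[[`, numeric(1), "n_decoys")) > n_lnc_acc)
    stop("more ceRNA decoys than accepted lncRNAs")
  cfg$seed <- as.integer(seed)
  cfg
}

# deterministic integer draw helpers (all flow from the caller's set.seed)
.runi <- function(n, lo, hi) lo + floor(stats::runif(n) * (hi - lo + 1))

#' Simulate a reference annotation and candidate transcripts
#'
#' Lays multi-exon protein-coding genes on two synthetic chromosomes
#' without overlaps, then plants candidate transcripts of each class
#' ('u' in intergenic gaps, 'x' overlapping a host exon antisense, 'i'
#' inside a long host intron, sense-overlap 'other') plus per-criterion
#' filter failures, and a CPC/Pfam score table consistent with the planted
#' labels. The first two genes are the focal CAM genes (PEPC-like,
#' PPCK-like).
#'
#' @param cfg Output of [simulationConfig()].
#' @return A list with \code{ref} and \code{candidates} (both
#'   \code{TranscriptSet}), \code{scores} (data.frame id/cpc_score/pfam_hit)
#'   and \code{truth} (data.frame of planted class code, biotype and
#'   violated criterion per candidate).
#' @export
simulateAnnotation <- function(cfg) {
  set.seed(cfg$seed)
  nG <- cfg$n_coding_genes
  gene_ids <- c("PEPC", "PPCK",
                sprintf("Aco%06d", seq_len(max(0, nG - 2))))[seq_len(nG)]
  chrom_of <- ifelse(seq_len(nG) <= ceiling(nG / 2), "chr1", "chr2")

  n_u <- cfg$n_lincRNA + sum(cfg$n_rejected_by)
  # host genes for x / i / sense-overlap candidates (skip the focal pair)
  hosts <- 2 + seq_len(cfg$n_lncNAT + cfg$n_intronic + cfg$n_sense_overlap)
  host_x <- hosts[seq_len(cfg$n_lncNAT)]
  host_i <- hosts[cfg$n_lncNAT + seq_len(cfg$n_intronic)]
  host_o <- hosts[cfg$n_lncNAT + cfg$n_intronic +
                  seq_len(cfg$n_sense_overlap)]

  genes <- vector("list", nG)
  gaps <- vector("list", nG)     # usable intergenic gap after each gene
  pos <- c(chr1 = 10000L, chr2 = 10000L)
  for (g in seq_len(nG)) {
    chr <- chrom_of[g]
    n_ex <- .runi(1, 3, 7)
    exw <- .runi(n_ex, 90, 300)
    need_big_intron <- g %in% host_i
    inw <- if (n_ex > 1) .runi(n_ex - 1, 300, 1500) else integer(0)
    if (need_big_intron && n_ex > 1) inw[.runi(1, 1, n_ex - 1)] <- 2500L
    starts <- pos[chr] + cumsum(c(0L, utils::head(exw, -1) + inw))
    ends <- starts + exw - 1L
    strand <- if (stats::runif(1) < 0.5) "+" else "-"
    genes[[g]] <- list(chr = chr, starts = starts, ends = ends,
                       strand = strand, exw = exw)
    gap <- 6000L
    gaps[[g]] <- c(ends[n_ex] + 1500L, ends[n_ex] + gap - 1500L)
    pos[chr] <- ends[n_ex] + gap
  }
  seqlens <- c(chr1 = unname(pos["chr1"]) + 20000,
               chr2 = unname(pos["chr2"]) + 20000)

  .mkGR <- function(chr, starts, ends, strand)
    GRanges(chr, IRanges(starts, ends), strand = strand,
            seqinfo = Seqinfo(c("chr1", "chr2"), seqlens))

  ref_ex <- lapply(genes, function(g)
    .mkGR(g$chr, g$starts, g$ends, g$strand))
  names(ref_ex) <- paste0(gene_ids, ".1")
  ref <- TranscriptSet(GRangesList(ref_ex, compress = TRUE),
                       geneId = gene_ids, biotype = "coding")

  # --- candidates -------------------------------------------------------
  cand <- list(); truth <- list()
  add <- function(id, gr, class, biotype, failure) {
    cand[[id]] <<- gr
    truth[[id]] <<- data.frame(id = id, class_code = class,
                               biotype = biotype, failure = failure)
  }
  kid <- 0L
  nextId <- function() {
    kid <<- kid + 1L
    sprintf("TCONS_%05d", kid)
  }

  # intergenic candidates, one per gap
  u_kind <- c(rep("lincRNA", cfg$n_lincRNA),
              rep(names(cfg$n_rejected_by), cfg$n_rejected_by))
  cpc_planted <- 0L  # first cpc failure sits exactly on the 0 boundary
  for (j in seq_along(u_kind)) {
    gap <- gaps[[j]]
    kind <- u_kind[j]
    chr <- genes[[j]]$chr
    strand <- if (kind == "unstranded") "*"
              else if (stats::runif(1) < 0.5) "+" else "-"
    s0 <- gap[1] + .runi(1, 0, 200)
    if (kind == "short") {
      gr <- .mkGR(chr, s0, s0 + .runi(1, 120, 199) - 1L, strand)
    } else if (kind == "low_fpkm" && j %% 2 == 0) {
      gr <- .mkGR(chr, s0, s0 + .runi(1, 300, 800) - 1L, strand) # mono-exon
    } else {
      n_ex <- .runi(1, 1, 3)
      exw <- .runi(n_ex, 150, 400)
      inw <- if (n_ex > 1) .runi(n_ex - 1, 100, 400) else integer(0)
      if (n_ex == 1 && sum(exw) <= 200) exw <- 250L
      starts <- s0 + cumsum(c(0L, utils::head(exw, -1) + inw))
      gr <- .mkGR(chr, starts, starts + exw - 1L, strand)
    }
    bio <- if (kind == "lincRNA") "lincRNA" else "rejected"
    failure <- if (kind == "lincRNA") "none" else kind
    add(nextId(), gr, "u", bio, failure)
  }

  # antisense exonic ('x') candidates over host exons
  for (h in host_x) {
    g <- genes[[h]]
    e <- max(1L, .runi(1, 1, length(g$starts)))
    anti <- if (g$strand == "+") "-" else "+"
    s0 <- g$starts[e] + max(0L, g$exw[e] %/% 2L - 1L)
    gr <- .mkGR(g$chr, s0, s0 + .runi(1, 250, 450) - 1L, anti)
    add(nextId(), gr, "x", "lncNAT", "none")
  }

  # intronic ('i') candidates inside the planted long intron
  sense_i <- rep(c(TRUE, FALSE), length.out = cfg$n_intronic)
  for (k in seq_along(host_i)) {
    g <- genes[[host_i[k]]]
    inl <- g$starts[-1] - (g$ends[-length(g$ends)] + 1L)
    ii <- which.max(inl)
    is0 <- g$ends[ii] + 1L
    s0 <- is0 + 300L
    w <- min(.runi(1, 300, 900), inl[ii] - 600L)
    strand <- if (sense_i[k]) g$strand else if (g$strand == "+") "-" else "+"
    add(nextId(), .mkGR(g$chr, s0, s0 + w - 1L, strand), "i",
        if (sense_i[k]) "lincRNA" else "lncNAT", "none")
  }

  # sense-overlap ('other') candidates
  for (h in host_o) {
    g <- genes[[h]]
    e <- max(1L, .runi(1, 1, length(g$starts)))
    s0 <- g$starts[e] + max(0L, g$exw[e] %/% 2L - 1L)
    gr <- .mkGR(g$chr, s0, s0 + .runi(1, 250, 450) - 1L, g$strand)
    add(nextId(), gr, "other", "rejected", "sense_overlap")
  }

  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  candidates <- TranscriptSet(GRangesList(cand, compress = TRUE),
                              geneId = paste0("XLOC_", names(cand)),
                              biotype = "candidate")

  cpc <- round(stats::runif(nrow(truth), -5, -0.5), 3)
  is_cpc <- truth$failure == "cpc"
  cpc[is_cpc] <- round(stats::runif(sum(is_cpc), 0, 3), 3)
  if (any(is_cpc)) cpc[which(is_cpc)[1]] <- 0   # pin the boundary case
  scores <- data.frame(id = truth$id, cpc_score = cpc,
                       pfam_hit = truth$failure == "pfam")
  list(ref = ref, candidates = candidates, scores = scores, truth = truth)
}

#' Simulate four-tissue expression with planted Tau labels
#'
#' Tissue-specific rows get one dominant tissue (FPKM 30-80) over a weak
#' background (< 0.8 FPKM), giving realized Tau well above 0.8; nonspecific
#' rows get a shared baseline (5-20 FPKM) across tissues plus optional
#' noise. The recorded truth Tau is the realized value computed from the
#' emitted numbers with [tauIndex()], not the requested target.
#'
#' @param cfg Output of [simulationConfig()].
#' @param ids Transcript ids for the matrix rows.
#' @return A list with \code{expr} (a \code{SummarizedExperiment}, one
#'   column per tissue) and \code{truth} (data.frame id / tau /
#'   specific_tissue / is_specific).
#' @export
simulateTissueExpression <- function(cfg, ids) {
  set.seed(cfg$seed + 1L)
  tis <- cfg$tissues
  n <- length(ids)
  n_spec <- min(cfg$n_specific_per_tissue * length(tis), n)
  # spread specific rows over the whole id vector (lncRNAs and mRNAs alike)
  spec_rows <- round(seq(1, n, length.out = n_spec))
  if (anyDuplicated(spec_rows)) spec_rows <- seq_len(n_spec)
  spec_tissue_of <- rep(NA_character_, n)
  spec_tissue_of[spec_rows] <- rep(tis, length.out = n_spec)
  m <- matrix(0, n, length(tis), dimnames = list(ids, tis))
  for (k in seq_len(n)) {
    if (!is.na(spec_tissue_of[k])) {
      bg <- stats::runif(length(tis), 0, 0.8)
      bg[match(spec_tissue_of[k], tis)] <- stats::runif(1, 30, 80)
      m[k, ] <- bg
    } else {
      m[k, ] <- stats::runif(1, 5, 20) +
        stats::rnorm(length(tis), 0, cfg$noise_sd)
    }
  }
  m <- pmax(m, 0)
  m <- round(m, 4)
  tau <- apply(m, 1, function(x) if (max(x) > 0) tauIndex(x) else NA_real_)
  truth <- data.frame(
    id = ids, tau = tau,
    specific_tissue = spec_tissue_of,
    is_specific = !is.na(spec_tissue_of))
  list(expr = fpkmExperiment(m, tissue = tis), truth = truth)
}

.unit01 <- function(v) (v - min(v)) / (max(v) - min(v))

.dielWave <- function(shape, phase, grid) {
  lib <- buildModelLibrary(grid)
  .unit01(lib$models[, sprintf("%s_p%g", shape, phase)])
}

#' Simulate two-tissue diel expression with planted cycling classes
#'
#' Every transcript gets a diel plan per tissue. Planted cyclers follow
#' baseline + amplitude x waveform (cosine, box or sawtooth at a library
#' phase), so max - min equals the planted amplitude exactly at zero noise.
#' Negative controls violate exactly one criterion: \code{flat} (constant),
#' \code{low_amplitude} (amplitude 3-8 FPKM), \code{low_fold_change}
#' (amplitude 12-20 over a 30-60 FPKM baseline). Transcripts planted as
#' low-expression filter failures stay below the detection FPKM floor in
#' both tissues. Values are replicated (\code{n_replicates} per time point)
#' with Gaussian noise of SD \code{noise_sd}, clipped at zero. The two
#' focal CAM genes cycle in the green tip only, flat and low in the white
#' base; a subset of mRNAs is coupled (exact affine copy, or mirrored copy
#' for negative edges) to the first planted green cyclers across the full
#' two-tissue condition series, seeding co-expression edges with |r| = 1 at
#' zero noise.
#'
#' @param cfg Output of [simulationConfig()].
#' @param lnc_ids Accepted-lncRNA candidate ids (cycling classes are
#'   planted among these).
#' @param other_cand_ids Named character vector id -> planted failure for
#'   the remaining candidates (\code{"low_fpkm_mono"},
#'   \code{"low_fpkm_multi"} or any other label for a plain baseline).
#' @param mrna_ids Reference transcript ids (the first two are the focal
#'   genes).
#' @return A list with \code{green} and \code{white}
#'   (\code{SummarizedExperiment}s with replicates), \code{truth} (per id
#'   and tissue: kind, shape, phase, baseline, amplitude, partner),
#'   \code{coexpr_truth} (planted lncRNA-mRNA couplings) and
#'   \code{lnc_cycling_class} (planted both/green-only/white-only/none).
#' @export
simulateDielExpression <- function(cfg, lnc_ids, other_cand_ids, mrna_ids) {
  set.seed(cfg$seed + 2L)
  grid <- sort(cfg$diel_grid)
  shapes <- c("cosine", "box", "sawtooth")
  phases <- seq(0, 22, by = 2)
  waves <- lapply(buildModelLibrary(grid)$models[, as.vector(outer(
    shapes, phases, function(s, p) sprintf("%s_p%g", s, p))),
    drop = FALSE] |> as.data.frame(), .unit01)

  plan <- list()
  addPlan <- function(id, tissue, kind, partner = NA_character_) {
    shape <- NA_character_; phase <- NA_real_; b <- 0; a <- 0
    if (kind %in% c("cycler", "low_amplitude", "low_fold_change")) {
      shape <- shapes[.runi(1, 1, 3)]
      phase <- phases[.runi(1, 1, length(phases))]
    }
    if (kind == "cycler") { b <- stats::runif(1, 0, 4)
                            a <- stats::runif(1, 12, 40) }
    if (kind == "low_amplitude") { b <- stats::runif(1, 0, 3)
                                   a <- stats::runif(1, 3, 8) }
    if (kind == "low_fold_change") { b <- stats::runif(1, 30, 60)
                                     a <- stats::runif(1, 12, 20) }
    if (kind == "flat") b <- stats::runif(1, 3, 15)
    if (kind == "baseline") b <- stats::runif(1, 3, 15)
    if (kind == "low_expr_mono") b <- stats::runif(1, 0.6, 1.4)
    if (kind == "low_expr_multi") b <- stats::runif(1, 0.05, 0.3)
    if (kind %in% c("couple", "mirror")) { b <- stats::runif(1, 0, 4)
                                           a <- stats::runif(1, 12, 30) }
    plan[[paste(id, tissue, sep = "|")]] <<- data.frame(
      id = id, tissue = tissue, kind = kind, shape = shape,
      phase = phase, baseline = round(b, 4), amplitude = round(a, 4),
      partner = partner)
  }

  cls <- c(rep("both", cfg$n_cycling["both"]),
           rep("green_only", cfg$n_cycling["green_only"]),
           rep("white_only", cfg$n_cycling["white_only"]),
           rep("neg_flat", cfg$n_cycling_neg["flat"]),
           rep("neg_low_amp", cfg$n_cycling_neg["low_amplitude"]),
           rep("neg_low_fc", cfg$n_cycling_neg["low_fold_change"]))
  cls <- c(cls, rep("none", length(lnc_ids) - length(cls)))
  for (k in seq_along(lnc_ids)) {
    id <- lnc_ids[k]
    addPlan(id, "green", switch(cls[k],
      both = "cycler", green_only = "cycler", white_only = "flat",
      neg_flat = "flat", neg_low_amp = "low_amplitude",
      neg_low_fc = "low_fold_change", none = "baseline"))
    addPlan(id, "white", switch(cls[k],
      both = "cycler", green_only = "flat", white_only = "cycler",
      neg_flat = "flat", neg_low_amp = "low_amplitude",
      neg_low_fc = "low_fold_change", none = "baseline"))
  }
  for (id in names(other_cand_ids)) {
    kind <- switch(other_cand_ids[[id]],
                   low_fpkm_mono = "low_expr_mono",
                   low_fpkm_multi = "low_expr_multi",
                   "baseline")
    addPlan(id, "green", kind)
    addPlan(id, "white", kind)
  }
  coex <- list()
  greenCyclers <- lnc_ids[cls %in% c("both", "green_only")]
  ci <- 0L
  for (j in seq_along(mrna_ids)) {
    id <- mrna_ids[j]
    if (j <= 2) {
      addPlan(id, "green", "cycler")
      addPlan(id, "white", "flat")
    } else if (ci < 2L * length(greenCyclers) && j %% 2 == 0) {
      ci <- ci + 1L
      partner <- greenCyclers[ceiling(ci / 2)]
      kind <- if (ci %% 2 == 0) "mirror" else "couple"
      addPlan(id, "green", kind, partner = partner)
      addPlan(id, "white", kind, partner = partner)
      coex[[length(coex) + 1L]] <- data.frame(
        lncrna = partner, mrna = id,
        sign = if (kind == "mirror") "negative" else "positive")
    } else {
      addPlan(id, "green", "baseline")
      addPlan(id, "white", "baseline")
    }
  }
  plan <- do.call(rbind, plan)
  rownames(plan) <- NULL

  all_ids <- unique(plan$id)
  nt <- length(grid)
  base <- list(green = matrix(0, length(all_ids), nt,
                              dimnames = list(all_ids, NULL)),
               white = matrix(0, length(all_ids), nt,
                              dimnames = list(all_ids, NULL)))
  direct <- plan[!(plan$kind %in% c("couple", "mirror")), ]
  for (k in seq_len(nrow(direct))) {
    p <- direct[k, ]
    v <- if (p$kind %in% c("cycler", "low_amplitude", "low_fold_change")) {
      p$baseline + p$amplitude * waves[[sprintf("%s_p%g", p$shape, p$phase)]]
    } else rep(p$baseline, nt)
    base[[p$tissue]][p$id, ] <- v
  }
  # coupled mRNAs: exact affine (or mirrored) copy of the partner lncRNA
  # over the combined two-tissue series, so |r| = 1 at zero noise
  coupled <- plan[plan$kind %in% c("couple", "mirror"), ]
  for (id in unique(coupled$id)) {
    p <- coupled[coupled$id == id & coupled$tissue == "green", ]
    lv <- c(base$green[p$partner, ], base$white[p$partner, ])
    norm <- .unit01(lv)
    if (p$kind == "mirror") norm <- 1 - norm
    v <- p$baseline + p$amplitude * norm
    base$green[id, ] <- v[seq_len(nt)]
    base$white[id, ] <- v[nt + seq_len(nt)]
  }

  .withReps <- function(m, tissue) {
    reps <- lapply(seq_len(cfg$n_replicates), function(r)
      pmax(m + matrix(stats::rnorm(length(m), 0, cfg$noise_sd), nrow(m)), 0))
    out <- round(do.call(cbind, reps), 4)
    colnames(out) <- as.vector(vapply(seq_len(cfg$n_replicates), function(r)
      sprintf("%s_h%g_r%d", tissue, grid, r), character(nt)))
    fpkmExperiment(out, tissue = tissue,
                   time_hour = rep(grid, cfg$n_replicates),
                   replicate = rep(seq_len(cfg$n_replicates), each = nt))
  }
  coexpr_truth <- if (length(coex)) do.call(rbind, coex)
                  else data.frame(lncrna = character(), mrna = character(),
                                  sign = character())
  list(green = .withReps(base$green, "green"),
       white = .withReps(base$white, "white"),
       truth = plan, coexpr_truth = coexpr_truth,
       lnc_cycling_class = stats::setNames(
         gsub("_", "-", sub("^neg_.*$", "none", cls)), lnc_ids))
}

#' Simulate miRNA binding tables with planted ceRNA triangles
#'
#' Each planted triangle binds the focal transcript in perfect mode by
#' \code{n_mirnas} miRNAs and mimic-binds \code{n_decoys} lncRNA decoys to
#' nonempty subsets of those miRNAs (each miRNA reaches at least one decoy,
#' so the competed set is the full planted set). Triangles use disjoint
#' miRNA sets, planted target-target mRNA pairs use their own miRNAs, and
#' background miRNAs bind a single transcript each, so no unintended shared
#' pairs arise.
#'
#' @param cfg Output of [simulationConfig()].
#' @param lnc_ids Accepted lncRNA ids (decoy pool).
#' @param mrna_ids Reference transcript ids (background/target-target pool).
#' @return A list with \code{bindings} (validated data.frame) and
#'   \code{truth} (data.frame focal / partner / pair_type / shared
#'   miRNAs, semicolon-joined).
#' @export
simulateBindings <- function(cfg, lnc_ids, mrna_ids) {
  set.seed(cfg$seed + 3L)
  rows <- list(); truth <- list()
  mir_k <- 0L
  nextMir <- function(n) {
    out <- sprintf("miR%04d", mir_k + seq_len(n))
    mir_k <<- mir_k + n
    out
  }
  decoy_pool <- lnc_ids
  for (tri in cfg$triangles) {
    m <- tri$n_mirnas; k <- tri$n_decoys
    if (k > length(decoy_pool)) stop("decoy pool exhausted")
    mirs <- nextMir(m)
    decoys <- decoy_pool[seq_len(k)]
    decoy_pool <- decoy_pool[-seq_len(k)]
    rows[[length(rows) + 1L]] <- data.frame(
      mirna = mirs, transcript = tri$focal, mode = "perfect")
    # round-robin guarantees every miRNA reaches >= 1 decoy when k >= m
    assign_sets <- lapply(seq_len(k), function(d) {
      extra <- mirs[stats::runif(m) < 0.3]
      unique(c(mirs[((d - 1L) %% m) + 1L], extra))
    })
    for (d in seq_len(k)) {
      rows[[length(rows) + 1L]] <- data.frame(
        mirna = assign_sets[[d]], transcript = decoys[d], mode = "mimic")
      truth[[length(truth) + 1L]] <- data.frame(
        focal = tri$focal, partner = decoys[d], pair_type = "target-mimic",
        shared_mirnas = paste(sort(assign_sets[[d]]), collapse = ";"))
    }
  }
  # planted target-target mRNA pairs
  tt_pool <- setdiff(mrna_ids,
                     vapply(cfg$triangles, `[[`, character(1), "focal"))
  for (j in seq_len(cfg$n_tt_pairs)) {
    if (length(tt_pool) < 2L) break
    mir <- nextMir(1)
    ab <- tt_pool[1:2]
    tt_pool <- tt_pool[-(1:2)]
    rows[[length(rows) + 1L]] <- data.frame(
      mirna = mir, transcript = ab, mode = "perfect")
    truth[[length(truth) + 1L]] <- data.frame(
      focal = ab[1], partner = ab[2], pair_type = "target-target",
      shared_mirnas = mir)
  }
  # background: one transcript per miRNA, no sharing possible
  bg_pool <- c(decoy_pool, tt_pool)
  if (cfg$n_background_mirnas > 0 && length(bg_pool)) {
    mirs <- nextMir(cfg$n_background_mirnas)
    tx <- bg_pool[.runi(cfg$n_background_mirnas, 1, length(bg_pool))]
    mode <- ifelse(stats::runif(cfg$n_background_mirnas) < 0.5,
                   "perfect", "mimic")
    rows[[length(rows) + 1L]] <- data.frame(
      mirna = mirs, transcript = tx, mode = mode)
  }
  bindings <- validateBindingTable(do.call(rbind, rows))
  truth <- if (length(truth)) do.call(rbind, truth)
           else data.frame(focal = character(), partner = character(),
                           pair_type = character(),
                           shared_mirnas = character())
  rownames(bindings) <- rownames(truth) <- NULL
  list(bindings = bindings, truth = truth)
}

#' Simulate the full synthetic study
#'
#' Runs all generators in sequence and assembles a ground-truth manifest.
#' Deterministic: the same configuration (including seed) yields identical
#' objects and identical files from [writeFixtures()].
#'
#' @param cfg Output of [simulationConfig()].
#' @return A list with \code{ref}, \code{candidates}, \code{scores},
#'   \code{tissue} (expr + truth), \code{diel} (green/white + truth),
#'   \code{bindings} (+ truth) and \code{truth}, the combined manifest.
#' @export
simulateCamLncData <- function(cfg) {
  ann <- simulateAnnotation(cfg)
  lnc_ids <- ann$truth$id[ann$truth$failure == "none"]
  other <- ann$truth$failure[ann$truth$failure != "none"]
  names(other) <- ann$truth$id[ann$truth$failure != "none"]
  # split the low-expression failures by exon count: single-exon rows sit in
  # [0.6, 1.4] FPKM (fail the 2-FPKM rule only), multi-exon ones below 0.5
  nex <- exonCounts(ann$candidates)
  is_low <- other == "low_fpkm"
  other[is_low] <- ifelse(nex[names(other)[is_low]] == 1L,
                          "low_fpkm_mono", "low_fpkm_multi")
  mrna_ids <- txIds(ann$ref)
  all_ids <- c(txIds(ann$candidates), mrna_ids)

  tis <- simulateTissueExpression(cfg, all_ids)
  diel <- simulateDielExpression(cfg, lnc_ids, other, mrna_ids)
  bnd <- simulateBindings(cfg, lnc_ids, mrna_ids)

  manifest <- list(
    seed = cfg$seed,
    transcripts = ann$truth,
    tau = tis$truth,
    diel_plan = diel$truth,
    cycling_class = data.frame(id = names(diel$lnc_cycling_class),
                               class = unname(diel$lnc_cycling_class)),
    coexpression = diel$coexpr_truth,
    cerna = bnd$truth)
  list(ref = ann$ref, candidates = ann$candidates, scores = ann$scores,
       tissue = tis, diel = diel, bindings = bnd, truth = manifest)
}

#' Write all simulated inputs as plain-text fixtures
#'
#' Emits \code{ref.gff3}, \code{candidates.gtf}, \code{scores.tsv},
#' \code{tissues.tsv}, \code{diel_green.tsv}/\code{diel_white.tsv} with
#' their sample sheets, \code{bindings.tsv} and the ground-truth manifest
#' \code{truth.json}.
#'
#' @param sim Output of [simulateCamLncData()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
writeFixtures <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  writeAnnotationGFF3(sim$ref, p("ref.gff3"))
  writeAnnotationGTF(sim$candidates, p("candidates.gtf"))
  write.table(sim$scores, p("scores.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeExpression(sim$tissue$expr, p("tissues.tsv"), p("tissues_samples.tsv"))
  writeExpression(sim$diel$green, p("diel_green.tsv"),
                  p("diel_green_samples.tsv"))
  writeExpression(sim$diel$white, p("diel_white.tsv"),
                  p("diel_white_samples.tsv"))
  writeBindingTable(sim$bindings$bindings, p("bindings.tsv"))
  jsonlite::write_json(sim$truth, p("truth.json"), dataframe = "columns",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  files <- c("ref.gff3", "candidates.gtf", "scores.tsv", "tissues.tsv",
             "tissues_samples.tsv", "diel_green.tsv",
             "diel_green_samples.tsv", "diel_white.tsv",
             "diel_white_samples.tsv", "bindings.tsv", "truth.json")
  invisible(stats::setNames(file.path(out_dir, files), files))
}

#' Write a TranscriptSet as GFF3 (gene/mRNA/exon hierarchy)
#'
#' @param x A \code{TranscriptSet}.
#' @param path Output path. Chromosome lengths are written as
#'   \code{##sequence-region} pragmas when known.
#' @return Invisibly, \code{path}.
#' @export
writeAnnotationGFF3 <- function(x, path) {
  spans <- txRanges(x)
  gspan <- geneRanges(x)
  gene_rows <- GRanges(seqnames(gspan), ranges(gspan), strand = strand(gspan),
                       seqinfo = seqinfo(gspan))
  mcols(gene_rows) <- DataFrame(type = "gene", ID = names(gspan))
  tx_rows <- GRanges(seqnames(spans), ranges(spans), strand = strand(spans),
                     seqinfo = seqinfo(spans))
  mcols(tx_rows) <- DataFrame(type = "mRNA", ID = txIds(x),
                              Parent = geneIds(x))
  flat <- unlist(x@exons, use.names = FALSE)
  nex <- S4Vectors::elementNROWS(x@exons)
  ex_rows <- flat
  mcols(ex_rows) <- DataFrame(type = "exon", Parent = rep(txIds(x), nex))
  all <- suppressWarnings(c(gene_rows, tx_rows, ex_rows))
  all <- all[order(as.character(seqnames(all)), start(all),
                   match(mcols(all)$type, c("gene", "mRNA", "exon")))]
  rtracklayer::export(all, path, format = "gff3")
  invisible(path)
}
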