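#' Configuration for diel-cycling detection
#'
#' A transcript is called cycling when its best correlation to any model
#' waveform strictly exceeds \code{r_threshold}, its fold change
#' (max + pseudocount)/(min + pseudocount) strictly exceeds
#' \code{min_fold_change}, its amplitude (max - min, FPKM) strictly exceeds
#' \code{min_amplitude}, and its permutation p-value is below
#' \code{p_threshold}. The p-value is estimated by shuffling time labels
#' \code{n_permutations} times and re-scoring against the same model
#' library, with a +1/(n+1) correction.
#'
#' @param r_threshold Strict correlation threshold (default 0.7).
#' @param min_fold_change Strict fold-change threshold (default 2).
#' @param min_amplitude Strict amplitude threshold in FPKM (default 10).
#' @param p_threshold Permutation p-value cutoff (default 0.05).
#' @param n_permutations Number of label shuffles, >= 100 (default 1000).
#' @param seed Integer RNG seed for the permutations.
#' @param pseudocount FPKM pseudocount guarding the fold-change ratio
#'   (default 1).
#' @return A named list.
#' @export
cyclingConfig <- function(r_threshold = 0.7, min_fold_change = 2,
                          min_amplitude = 10, p_threshold = 0.05,
                          n_permutations = 1000, seed = 1,
                          pseudocount = 1) {
  if (any(c(r_threshold, min_fold_change, min_amplitude, p_threshold,
            pseudocount) <= 0))
    stop("thresholds must be positive")
  if (n_permutations < 100)
    stop("n_permutations must be >= 100")
  list(r_threshold = r_threshold, min_fold_change = min_fold_change,
       min_amplitude = min_amplitude, p_threshold = p_threshold,
       n_permutations = as.integer(n_permutations), seed = as.integer(seed),
       pseudocount = pseudocount)
}

#' Build a library of phase-shifted cycling model waveforms
#'
#' Four canonical 24-h shapes evaluated on the actual (possibly uneven)
#' sampling grid, each at every phase offset from 0 to just below 24 h in
#' steps of \code{phase_step_hours}: cosine
#' \eqn{\cos(2\pi (t-\phi)/24)}; spike, 1 at the grid point circularly
#' nearest \eqn{\phi} and 0 elsewhere; box, 1 where
#' \eqn{(t-\phi) \bmod 24 < 12}; and sawtooth,
#' \eqn{1 - ((t-\phi) \bmod 24)/24}. Constant vectors (possible on sparse
#' grids) are dropped.
#'
#' @param time_grid Clock hours of the samples, >= 6 points within one 24-h
#'   period.
#' @param phase_step_hours Phase resolution in hours (default 2).
#' @return A list with \code{time_grid} and \code{models}, a numeric matrix
#'   (grid points x models) with columns named \code{shape_p<phase>}.
#' @export
buildModelLibrary <- function(time_grid, phase_step_hours = 2) {
  if (length(time_grid) < 6L)
    stop("time grid needs at least 6 points")
  t <- as.numeric(time_grid)
  phases <- seq(0, 24 - phase_step_hours, by = phase_step_hours)
  cols <- list()
  for (phi in phases) {
    d <- (t - phi) %% 24
    circ <- pmin(d, 24 - d)
    spike <- as.numeric(seq_along(t) == which.min(circ))
    vals <- list(cosine = cos(2 * pi * (t - phi) / 24),
                 spike = spike,
                 box = as.numeric(d < 12),
                 sawtooth = 1 - d / 24)
    for (s in names(vals))
      cols[[sprintf("%s_p%g", s, phi)]] <- vals[[s]]
  }
  m <- do.call(cbind, cols)
  m <- m[, apply(m, 2, stats::sd) > 0, drop = FALSE]
  list(time_grid = t, models = m)
}

.bestModelR <- function(profile, models) {
  r <- suppressWarnings(stats::cor(profile, models))
  k <- which.max(r)
  list(r = r[k], model = colnames(models)[k])
}

#' Score one diel profile against the model library
#'
#' Computes the best model correlation, fold change, amplitude and
#' permutation p-value for a single replicate-averaged diel profile, and
#' applies the four cycling criteria (see [cyclingConfig()]). A constant
#' profile has undefined correlation and is reported as non-cycling with
#' reason \code{"zero variance"}.
#'
#' @param profile Non-negative numeric vector, one value per grid point.
#' @param lib Output of [buildModelLibrary()]; its grid length must match.
#' @param cfg Output of [cyclingConfig()]. The seed is applied before the
#'   permutations, making the p-value reproducible.
#' @return A one-row data.frame with columns \code{model}, \code{phase},
#'   \code{r}, \code{fold_change}, \code{amplitude}, \code{p},
#'   \code{is_cycling}, \code{reason}.
#' @export
scoreProfile <- function(profile, lib, cfg = cyclingConfig()) {
  if (length(profile) != nrow(lib$models))
    stop("profile length must equal the model grid length")
  if (any(profile < 0)) stop("profile must be non-negative")
  if (!is.null(cfg$seed) && !is.na(cfg$seed)) set.seed(cfg$seed)
  .scoreProfileNoSeed(profile, lib, cfg)
}

.scoreProfileNoSeed <- function(profile, lib, cfg) {
  hi <- max(profile); lo <- min(profile)
  fc <- (hi + cfg$pseudocount) / (lo + cfg$pseudocount)
  amp <- hi - lo
  if (stats::sd(profile) == 0)
    return(data.frame(model = NA_character_, phase = NA_real_, r = NA_real_,
                      fold_change = fc, amplitude = amp, p = NA_real_,
                      is_cycling = FALSE, reason = "zero variance"))
  best <- .bestModelR(profile, lib$models)
  B <- cfg$n_permutations
  perms <- matrix(profile[vapply(seq_len(B), function(i)
    sample.int(length(profile)), integer(length(profile)))], ncol = B)
  pr <- suppressWarnings(stats::cor(perms, lib$models))
  perm_best <- apply(pr, 1, max, na.rm = TRUE)
  p <- (sum(perm_best >= best$r) + 1) / (B + 1)
  phase <- as.numeric(sub("^.*_p", "", best$model))
  shape <- sub("_p.*$", "", best$model)
  cyc <- best$r > cfg$r_threshold && fc > cfg$min_fold_change &&
    amp > cfg$min_amplitude && p < cfg$p_threshold
  data.frame(model = shape, phase = phase, r = best$r, fold_change = fc,
             amplitude = amp, p = p, is_cycling = cyc, reason = "")
}

#' Score every transcript of a diel matrix for cycling
#'
#' Replicate-collapses the input if needed, orders columns by clock hour,
#' and applies [scoreProfile()] to every row. One RNG seed (from
#' \code{cfg$seed}) governs all permutations, so the full call set is
#' reproducible.
#'
#' @param expr A \code{SummarizedExperiment} of one tissue's diel series
#'   (or a matrix whose columns are already time-ordered conditions, with a
#'   \code{time_grid} attribute or matching \code{lib$time_grid} length).
#' @param lib Output of [buildModelLibrary()].
#' @param cfg Output of [cyclingConfig()].
#' @param tissue Tissue label recorded in the output.
#' @return A data.frame with one row per transcript: \code{transcript},
#'   \code{tissue}, then the [scoreProfile()] columns.
#' @export
scoreCycling <- function(expr, lib, cfg = cyclingConfig(), tissue = NA) {
  if (is.matrix(expr)) {
    m <- expr
  } else {
    if (!all(is.na(colData(expr)$replicate)))
      expr <- collapseReplicates(expr)
    ord <- order(colData(expr)$time_hour)
    m <- assay(expr, "fpkm")[, ord, drop = FALSE]
    if (is.na(tissue)) tissue <- colData(expr)$tissue[1]
  }
  if (ncol(m) != nrow(lib$models))
    stop("number of time points must equal the model grid length")
  set.seed(cfg$seed)
  calls <- do.call(rbind, lapply(seq_len(nrow(m)), function(k)
    .scoreProfileNoSeed(m[k, ], lib, cfg)))
  cbind(data.frame(transcript = rownames(m), tissue = tissue), calls)
}

#' Classify cycling overlap between two tissues
#'
#' Partitions a shared transcript universe into \code{"both"},
#' \code{"green-only"}, \code{"white-only"} and \code{"none"} according to
#' the cycling calls in the green leaf tip and white leaf base series.
#'
#' @param green_calls,white_calls Data.frames from [scoreCycling()] over the
#'   same transcript universe.
#' @return A data.frame with columns \code{transcript} and \code{class}.
#' @export
classifyOverlap <- function(green_calls, white_calls) {
  if (!setequal(green_calls$transcript, white_calls$transcript))
    stop("green and white call sets cover different transcript universes")
  ids <- green_calls$transcript
  g <- green_calls$is_cycling[match(ids, green_calls$transcript)]
  w <- white_calls$is_cycling[match(ids, white_calls$transcript)]
  cls <- ifelse(g & w, "both",
         ifelse(g, "green-only",
         ifelse(w, "white-only", "none")))
  data.frame(transcript = ids, class = cls)
}
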