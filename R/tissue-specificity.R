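#' Tau tissue-specificity index
#'
#' For an expression profile \eqn{x_1, \dots, x_N} over \eqn{N \ge 2}
#' tissues, each component is normalized by the profile maximum,
#' \eqn{\hat{x}_i = x_i / \max_j x_j}, and
#' \deqn{\tau = \frac{\sum_{i=1}^{N} (1 - \hat{x}_i)}{N - 1}.}
#' Tau is 0 for a perfectly uniform profile and 1 when exactly one tissue is
#' expressed; it is invariant to rescaling the whole profile.
#'
#' @param profile Non-negative numeric vector, length >= 2, not all zero.
#' @return Tau in \[0, 1\].
#' @examples
#' tauIndex(c(5, 5, 5, 5))   # 0
#' tauIndex(c(0, 0, 7))      # 1
#' tauIndex(c(1, 2, 4, 8))   # 2.125 / 3
#' @export
tauIndex <- function(profile) {
  .checkProfile(profile)
  xhat <- profile / max(profile)
  sum(1 - xhat) / (length(profile) - 1)
}

#' Shannon-entropy tissue-specificity score
#'
#' The expression profile is normalized to proportions
#' \eqn{p_i = x_i / \sum_j x_j} and scored by Shannon entropy in bits,
#' \eqn{H_g = -\sum_i p_i \log_2 p_i} with \eqn{0 \log 0 := 0}. Low entropy
#' means high tissue specificity; the maximum, \eqn{\log_2 N}, is reached by
#' a uniform profile.
#'
#' @inheritParams tauIndex
#' @return Entropy in bits, in \[0, log2(N)\].
#' @export
hgEntropy <- function(profile) {
  .checkProfile(profile)
  p <- profile / sum(profile)
  p <- p[p > 0]
  -sum(p * log2(p))
}

.checkProfile <- function(profile) {
  if (length(profile) < 2L)
    stop("profile needs at least 2 tissues")
  if (any(is.na(profile)) || any(profile < 0))
    stop("profile must be non-negative and non-missing")
  if (max(profile) == 0)
    stop("all-zero profile: specificity undefined")
  invisible(TRUE)
}

#' Configuration for tissue-specificity calling
#'
#' @param min_fpkm_any_tissue Rows whose maximum FPKM over tissues is below
#'   this are discarded before scoring (default 1).
#' @param tau_threshold Strict lower bound on Tau for a tissue-specific call
#'   (default 0.8).
#' @param expressed_threshold FPKM at or above which a transcript counts as
#'   expressed in a tissue, used for unique-expression calls (default 1).
#' @return A named list.
#' @export
specificityConfig <- function(min_fpkm_any_tissue = 1,
                              tau_threshold = 0.8,
                              expressed_threshold = 1) {
  cfg <- list(min_fpkm_any_tissue = min_fpkm_any_tissue,
              tau_threshold = tau_threshold,
              expressed_threshold = expressed_threshold)
  if (any(unlist(cfg) < 0)) stop("thresholds must be >= 0")
  cfg
}

#' Call tissue-specific and uniquely expressed transcripts
#'
#' Scores each transcript's per-tissue profile with [tauIndex()] and
#' [hgEntropy()] after discarding transcripts below the expression floor
#' (max FPKM < \code{min_fpkm_any_tissue} across all tissues). A transcript
#' is tissue-specific when Tau strictly exceeds \code{tau_threshold}; its
#' assigned tissue is the profile argmax (ties leave the tissue unassigned).
#' It is uniquely expressed when it reaches \code{expressed_threshold} in
#' exactly one tissue. The input must already have one column per tissue
#' (multi-stage tissues such as fruit pre-averaged to a single column).
#'
#' @param expr A \code{SummarizedExperiment} with one column per tissue
#'   (>= 2 tissues), or a numeric matrix with tissue column names.
#' @param cfg Output of [specificityConfig()].
#' @return A data.frame with columns \code{transcript}, \code{tau},
#'   \code{hg_entropy}, \code{max_tissue} (NA on ties),
#'   \code{is_tissue_specific}, \code{is_uniquely_expressed}; one row per
#'   retained transcript.
#' @export
callSpecificity <- function(expr, cfg = specificityConfig()) {
  m <- if (is.matrix(expr)) expr else assay(expr, "fpkm")
  if (ncol(m) < 2L)
    stop("at least 2 tissue columns are required")
  tissues <- colnames(m)
  keep <- apply(m, 1, max) >= cfg$min_fpkm_any_tissue
  m <- m[keep, , drop = FALSE]
  if (!nrow(m))
    return(data.frame(transcript = character(), tau = numeric(),
                      hg_entropy = numeric(), max_tissue = character(),
                      is_tissue_specific = logical(),
                      is_uniquely_expressed = logical()))
  tau <- apply(m, 1, tauIndex)
  hg <- apply(m, 1, hgEntropy)
  max_tissue <- apply(m, 1, function(x) {
    top <- which(x == max(x))
    if (length(top) == 1L) tissues[top] else NA_character_
  })
  n_expressed <- rowSums(m >= cfg$expressed_threshold)
  data.frame(transcript = rownames(m),
             tau = tau,
             hg_entropy = hg,
             max_tissue = max_tissue,
             is_tissue_specific = tau > cfg$tau_threshold,
             is_uniquely_expressed = n_expressed == 1L,
             row.names = NULL)
}
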