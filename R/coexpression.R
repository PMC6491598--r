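#' Pearson correlation between two expression profiles
#'
#' Standard product-moment correlation, exposed for edge verification.
#'
#' @param a,b Numeric vectors of equal length >= 3 with nonzero variance.
#' @return r in \[-1, 1\].
#' @export
pearsonR <- function(a, b) {
  if (length(a) != length(b) || length(a) < 3L)
    stop("profiles must have equal length >= 3")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero-variance profile: correlation undefined")
  stats::cor(a, b)
}

#' Build a lncRNA-mRNA co-expression network by correlation thresholding
#'
#' Computes Pearson correlations between every lncRNA and every mRNA across
#' the shared condition columns (replicate-collapsed diel conditions) and
#' keeps edges with r strictly above \code{r_threshold} or strictly below
#' \code{-r_threshold}. Zero-variance profiles cannot be correlated; pairs
#' involving them are skipped and the skip count recorded.
#'
#' @param lnc_expr,mrna_expr \code{SummarizedExperiment}s (or matrices) with
#'   identical sample columns.
#' @param r_threshold Strict absolute-correlation threshold (default 0.95).
#' @return A data.frame of edges with columns \code{lncrna}, \code{mrna},
#'   \code{r}, \code{sign} (\code{"positive"}/\code{"negative"}), carrying
#'   attributes \code{n_skipped_pairs} and \code{r_threshold}.
#' @export
buildCoexpressionNetwork <- function(lnc_expr, mrna_expr, r_threshold = 0.95) {
  L <- if (is.matrix(lnc_expr)) lnc_expr else assay(lnc_expr, "fpkm")
  M <- if (is.matrix(mrna_expr)) mrna_expr else assay(mrna_expr, "fpkm")
  if (!identical(colnames(L), colnames(M)))
    stop("lncRNA and mRNA matrices must share identical sample columns")
  if (ncol(L) < 3L)
    stop("at least 3 shared samples are required")
  sdL <- apply(L, 1, stats::sd)
  sdM <- apply(M, 1, stats::sd)
  okL <- sdL > 0
  okM <- sdM > 0
  n_skipped <- sum(!okL) * nrow(M) + sum(okL) * sum(!okM)
  edges <- data.frame(lncrna = character(), mrna = character(),
                      r = numeric(), sign = character())
  if (any(okL) && any(okM)) {
    r <- stats::cor(t(L[okL, , drop = FALSE]), t(M[okM, , drop = FALSE]))
    hit <- which(abs(r) > r_threshold, arr.ind = TRUE)
    if (nrow(hit)) {
      rv <- r[hit]
      edges <- data.frame(
        lncrna = rownames(r)[hit[, 1]],
        mrna = colnames(r)[hit[, 2]],
        r = rv,
        sign = ifelse(rv > 0, "positive", "negative"))
      edges <- edges[order(edges$lncrna, edges$mrna), , drop = FALSE]
      rownames(edges) <- NULL
    }
  }
  attr(edges, "n_skipped_pairs") <- n_skipped
  attr(edges, "r_threshold") <- r_threshold
  edges
}

#' Extract the subnetwork induced by a node set
#'
#' Keeps edges whose both endpoints belong to \code{node_ids}; used e.g. to
#' project a differentially-expressed gene/lncRNA list onto the full
#' network. Idempotent; an empty result is allowed.
#'
#' @param net Edge data.frame from [buildCoexpressionNetwork()].
#' @param node_ids Non-empty character vector of node ids.
#' @return Edge data.frame of the induced subnetwork, with attributes
#'   \code{n_positive} and \code{n_negative}.
#' @export
inducedSubnetwork <- function(net, node_ids) {
  if (!length(node_ids)) stop("node_ids must be non-empty")
  sub <- net[net$lncrna %in% node_ids & net$mrna %in% node_ids, , drop = FALSE]
  rownames(sub) <- NULL
  attr(sub, "n_positive") <- sum(sub$sign == "positive")
  attr(sub, "n_negative") <- sum(sub$sign == "negative")
  sub
}

#' Bipartite degree summary of a co-expression network
#'
#' @param net Edge data.frame from [buildCoexpressionNetwork()].
#' @return A data.frame with columns \code{node}, \code{class}
#'   (\code{"lncRNA"}/\code{"mRNA"}), \code{degree}, carrying an attribute
#'   \code{range} with the min/max degree per class.
#' @export
degreeSummary <- function(net) {
  dl <- table(net$lncrna)
  dm <- table(net$mrna)
  out <- rbind(
    data.frame(node = names(dl), class = "lncRNA",
               degree = as.integer(dl)),
    data.frame(node = names(dm), class = "mRNA",
               degree = as.integer(dm)))
  rownames(out) <- NULL
  attr(out, "range") <- list(
    lncRNA = if (length(dl)) range(as.integer(dl)) else c(NA, NA),
    mRNA = if (length(dm)) range(as.integer(dm)) else c(NA, NA))
  out
}

#' Write a co-expression network as GraphML
#'
#' Plain-text GraphML suitable for Cytoscape-style viewers; nodes carry a
#' \code{class} attribute, edges carry \code{r} and \code{sign}.
#'
#' @param net Edge data.frame from [buildCoexpressionNetwork()].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeCoexpressionGraphML <- function(net, path) {
  nodes <- rbind(data.frame(id = unique(net$lncrna), class = "lncRNA"),
                 data.frame(id = unique(net$mrna), class = "mRNA"))
  edges <- data.frame(source = net$lncrna, target = net$mrna,
                      attrs = sprintf(
                        '<data key="r">%.6g</data><data key="sign">%s</data>',
                        net$r, net$sign))
  .writeGraphML(nodes, edges,
                edge_keys = '<key id="r" for="edge" attr.name="r" attr.type="double"/>\n<key id="sign" for="edge" attr.name="sign" attr.type="string"/>',
                path = path)
}

.writeGraphML <- function(nodes, edges, edge_keys, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '<key id="class" for="node" attr.name="class" attr.type="string"/>',
    edge_keys,
    '<graph edgedefault="undirected">'), con)
  if (nrow(nodes))
    writeLines(sprintf('<node id="%s"><data key="class">%s</data></node>',
                       nodes$id, nodes$class), con)
  if (nrow(edges))
    writeLines(sprintf('<edge source="%s" target="%s">%s</edge>',
                       edges$source, edges$target, edges$attrs), con)
  writeLines(c('</graph>', '</graphml>'), con)
  invisible(path)
}
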