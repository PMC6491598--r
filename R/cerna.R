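#' Competing endogenous RNA pairs from shared miRNA binding
#'
#' Two transcripts form a ceRNA pair when at least one miRNA binds both of
#' them. For each unordered pair the full shared-miRNA set is reported and
#' the pair is typed by the strongest shared evidence: \code{"target-target"}
#' if some shared miRNA binds both transcripts in perfect mode,
#' \code{"target-mimic"} if the strongest shared link couples one perfect
#' and one mimic site. Pairs whose shared miRNAs link them only through
#' mimic-mimic sites are excluded by default (set
#' \code{include_mimic_mimic = TRUE} to keep them typed
#' \code{"mimic-mimic"}).
#'
#' @param bindings A binding table (see [readBindingTable()]).
#' @param include_mimic_mimic Keep pairs supported only by mimic-mimic
#'   links (default FALSE).
#' @return A data.frame with columns \code{transcript_a},
#'   \code{transcript_b} (a < b lexicographically), \code{pair_type},
#'   \code{n_shared} and a list column \code{shared_mirnas}.
#' @export
sharedMirnaPairs <- function(bindings, include_mimic_mimic = FALSE) {
  bindings <- validateBindingTable(bindings)
  empty <- data.frame(transcript_a = character(), transcript_b = character(),
                      pair_type = character(), n_shared = integer())
  empty$shared_mirnas <- I(list())
  if (!nrow(bindings)) return(empty)

  # per miRNA, the transcripts it binds and in which modes
  by_mirna <- split(bindings[, c("transcript", "mode")], bindings$mirna)
  acc <- new.env(parent = emptyenv())
  for (mir in names(by_mirna)) {
    tab <- by_mirna[[mir]]
    txs <- unique(tab$transcript)
    if (length(txs) < 2L) next
    perfect <- unique(tab$transcript[tab$mode == "perfect"])
    mimic <- unique(tab$transcript[tab$mode == "mimic"])
    cmb <- utils::combn(sort(txs), 2L)
    for (j in seq_len(ncol(cmb))) {
      a <- cmb[1L, j]; b <- cmb[2L, j]
      # strongest link this miRNA provides for (a, b)
      link <- if (a %in% perfect && b %in% perfect) "tt"
              else if ((a %in% perfect && b %in% mimic) ||
                       (b %in% perfect && a %in% mimic)) "tm"
              else "mm"
      key <- paste(a, b, sep = "\r")
      cur <- acc[[key]]
      if (is.null(cur)) cur <- list(mirnas = character(), links = character())
      cur$mirnas <- c(cur$mirnas, mir)
      cur$links <- c(cur$links, link)
      acc[[key]] <- cur
    }
  }
  keys <- sort(ls(acc))
  if (!length(keys)) return(empty)
  rows <- lapply(keys, function(key) {
    cur <- acc[[key]]
    type <- if ("tt" %in% cur$links) "target-target"
            else if ("tm" %in% cur$links) "target-mimic"
            else "mimic-mimic"
    ab <- strsplit(key, "\r", fixed = TRUE)[[1]]
    df <- data.frame(transcript_a = ab[1], transcript_b = ab[2],
                     pair_type = type, n_shared = length(unique(cur$mirnas)))
    df$shared_mirnas <- I(list(sort(unique(cur$mirnas))))
    df
  })
  out <- do.call(rbind, rows)
  if (!include_mimic_mimic)
    out <- out[out$pair_type != "mimic-mimic", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' ceRNA partners of a focal transcript
#'
#' Returns every transcript that forms a ceRNA pair with the focal
#' transcript (e.g. a CAM pathway gene such as PEPC or PPCK), together with
#' the union of miRNAs competed over.
#'
#' @inheritParams sharedMirnaPairs
#' @param focal_id Transcript id present in the binding table.
#' @return A list with \code{partners} (character), \code{competed_mirnas}
#'   (character) and \code{pairs} (the focal rows of [sharedMirnaPairs()]).
#' @export
focalCerna <- function(bindings, focal_id, include_mimic_mimic = FALSE) {
  bindings <- validateBindingTable(bindings)
  if (!focal_id %in% bindings$transcript)
    stop("focal transcript not present in binding table: ", focal_id)
  pairs <- sharedMirnaPairs(bindings, include_mimic_mimic)
  hit <- pairs$transcript_a == focal_id | pairs$transcript_b == focal_id
  sub <- pairs[hit, , drop = FALSE]
  partners <- ifelse(sub$transcript_a == focal_id,
                     sub$transcript_b, sub$transcript_a)
  list(partners = unname(partners),
       competed_mirnas = sort(unique(unlist(sub$shared_mirnas))),
       pairs = sub)
}

#' Export a ceRNA network as GraphML
#'
#' Tripartite plain-text GraphML: miRNA nodes, transcript nodes (typed
#' mRNA/lincRNA/lncNAT) and miRNA-transcript edges derived from the shared
#' sets of the given pairs, plus typed ceRNA pair edges.
#'
#' @param pairs Output of [sharedMirnaPairs()].
#' @param node_classes Named character vector mapping every transcript id in
#'   \code{pairs} to \code{"mRNA"}, \code{"lincRNA"} or \code{"lncNAT"}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeCernaGraphML <- function(pairs, node_classes, path) {
  txs <- unique(c(pairs$transcript_a, pairs$transcript_b))
  unknown <- setdiff(txs, names(node_classes))
  if (length(unknown))
    stop("unclassified node(s): ", paste(unknown, collapse = ", "))
  mirnas <- sort(unique(unlist(pairs$shared_mirnas)))
  nodes <- rbind(
    if (length(txs)) data.frame(id = txs,
                                class = unname(node_classes[txs]))
    else data.frame(id = character(), class = character()),
    if (length(mirnas)) data.frame(id = mirnas, class = "miRNA")
    else data.frame(id = character(), class = character()))
  mir_edges <- if (nrow(pairs)) unique(do.call(rbind, lapply(
    seq_len(nrow(pairs)), function(k)
      data.frame(source = pairs$shared_mirnas[[k]],
                 target = rep(c(pairs$transcript_a[k], pairs$transcript_b[k]),
                              each = length(pairs$shared_mirnas[[k]])),
                 attrs = '<data key="type">binding</data>'))))
    else data.frame(source = character(), target = character(),
                    attrs = character())
  pair_edges <- data.frame(
    source = pairs$transcript_a, target = pairs$transcript_b,
    attrs = sprintf('<data key="type">%s</data>', pairs$pair_type))
  .writeGraphML(nodes, rbind(mir_edges, pair_edges),
                edge_keys = '<key id="type" for="edge" attr.name="type" attr.type="string"/>',
                path = path)
}

#' Write ceRNA pairs as TSV
#'
#' @param pairs Output of [sharedMirnaPairs()].
#' @param path Output path. Shared miRNA sets are semicolon-joined.
#' @return Invisibly, \code{path}.
#' @export
writeCernaPairs <- function(pairs, path) {
  out <- data.frame(
    transcript_a = pairs$transcript_a,
    transcript_b = pairs$transcript_b,
    pair_type = pairs$pair_type,
    shared_mirnas = vapply(pairs$shared_mirnas, paste,
                           character(1), collapse = ";"))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
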