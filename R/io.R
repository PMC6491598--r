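#' @importFrom rtracklayer import export
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importFrom utils read.delim write.table
NULL

#' Read a transcript annotation (GTF or GFF3)
#'
#' Parses exon features from a GTF or GFF3 file into a
#' \linkS4class{TranscriptSet}. For GTF, transcript and gene identity come
#' from the \code{transcript_id}/\code{gene_id} attributes; for GFF3 they are
#' resolved through \code{Parent} links (exon -> transcript -> gene).
#' Exons are grouped per transcript and sorted by start. If the file declares
#' chromosome lengths (GFF3 \code{##sequence-region} pragmas), exons are
#' validated against them. Optional \code{class_code} and \code{biotype}
#' attributes written by [writeAnnotationGTF()] are restored, so a
#' write-then-read round trip preserves the full feature set.
#'
#' Coordinates are 1-based inclusive (the GTF convention) throughout the
#' package.
#'
#' @param path Path to a \code{.gtf}, \code{.gff} or \code{.gff3} file.
#' @param biotype Default biotype for transcripts lacking a biotype
#'   attribute (default \code{"coding"}, suitable for reference annotations).
#' @return A \code{TranscriptSet}.
#' @export
readAnnotation <- function(path, biotype = "coding") {
  if (!file.exists(path))
    stop("annotation file not found: ", path)
  gr <- tryCatch(rtracklayer::import(path),
                 error = function(e) stop("failed to parse ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  mc <- mcols(gr)
  is_exon <- !is.null(mc$type) & tolower(as.character(mc$type)) == "exon"
  ex <- gr[is_exon]
  if (!length(ex))
    stop("no exon features found in ", path)
  mce <- mcols(ex)
  if (!is.null(mce$transcript_id)) {           # GTF route
    tx <- as.character(mce$transcript_id)
    gene <- if (!is.null(mce$gene_id)) as.character(mce$gene_id) else tx
  } else if (!is.null(mce$Parent)) {           # GFF3 route
    tx <- vapply(mce$Parent, function(p) sub("^transcript:", "", p[1]),
                 character(1))
    parents <- gr[!is_exon]
    pid <- as.character(mcols(parents)$ID)
    keep <- !is.na(pid)
    parents <- parents[keep]
    pid <- pid[keep]
    pparent <- vapply(mcols(parents)$Parent, function(p)
      if (length(p)) sub("^gene:", "", p[1]) else NA_character_, character(1))
    pmap <- stats::setNames(pparent, sub("^transcript:", "", pid))
    gene <- unname(pmap[tx])
    gene[is.na(gene)] <- tx[is.na(gene)]
  } else {
    stop("exon features carry neither transcript_id nor Parent attributes")
  }
  cc <- if (!is.null(mce$class_code)) as.character(mce$class_code)
        else rep("none", length(ex))
  bt <- if (!is.null(mce$biotype)) as.character(mce$biotype)
        else rep(biotype, length(ex))
  mcols(ex) <- NULL
  spl <- split(ex, tx)
  first <- !duplicated(tx)
  ord <- names(spl)
  TranscriptSet(spl,
    geneId = gene[first][match(ord, tx[first])],
    classCode = cc[first][match(ord, tx[first])],
    biotype = bt[first][match(ord, tx[first])])
}

#' Write a TranscriptSet as GTF
#'
#' Emits one \code{exon} feature line per exon with \code{gene_id},
#' \code{transcript_id}, \code{class_code} and \code{biotype} attributes.
#'
#' @param x A \code{TranscriptSet}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeAnnotationGTF <- function(x, path) {
  ex <- x@exons
  flat <- unlist(ex, use.names = FALSE)
  nex <- S4Vectors::elementNROWS(ex)
  mcols(flat) <- DataFrame(
    type = "exon",
    gene_id = rep(geneIds(x), nex),
    transcript_id = rep(txIds(x), nex),
    class_code = rep(classCode(x), nex),
    biotype = rep(txBiotype(x), nex))
  rtracklayer::export(flat, path, format = "gtf")
  invisible(path)
}

#' Build an FPKM SummarizedExperiment
#'
#' Thin validated constructor for the expression container used throughout:
#' a \code{SummarizedExperiment} with a single \code{"fpkm"} assay and
#' per-sample metadata columns \code{tissue}, \code{time_hour},
#' \code{replicate}.
#'
#' @param values Numeric matrix, transcripts x samples, non-negative FPKM.
#'   Row and column names are required and must be unique.
#' @param tissue Character vector of tissue labels, one per column.
#' @param time_hour Clock hour in \[0, 24) per column, or \code{NA} for
#'   non-time-course samples. Must be all present or all absent.
#' @param replicate Integer replicate label per column, or \code{NA}.
#' @return A \code{SummarizedExperiment}.
#' @export
fpkmExperiment <- function(values, tissue,
                           time_hour = NA_real_, replicate = NA_integer_) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("FPKM matrix needs row (transcript) and column (sample) names")
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values)))
    stop("row and column names must be unique")
  if (any(is.na(values)) || any(values < 0))
    stop("FPKM values must be non-negative and non-missing")
  n <- ncol(values)
  th <- rep(as.numeric(time_hour), length.out = n)
  if (any(is.na(th)) && !all(is.na(th)))
    stop("time_hour must be present for all samples or none")
  if (any(!is.na(th) & (th < 0 | th >= 24)))
    stop("time_hour must lie in [0, 24)")
  cd <- DataFrame(
    tissue = rep(as.character(tissue), length.out = n),
    time_hour = th,
    replicate = rep(as.integer(replicate), length.out = n),
    row.names = colnames(values))
  SummarizedExperiment(assays = list(fpkm = values), colData = cd)
}

#' Read an expression matrix with its sample sheet
#'
#' The matrix is a tab-delimited table whose first column holds transcript
#' ids and whose remaining columns are numeric FPKM values; the sample sheet
#' is a tab-delimited table with columns \code{sample}, \code{tissue},
#' \code{time_hour}, \code{replicate}. Every matrix column must appear in
#' the sheet. Negative or non-numeric cells are rejected.
#'
#' @param path Path to the expression TSV.
#' @param sampleSheet Path to the sample sheet TSV.
#' @return A \code{SummarizedExperiment} (see [fpkmExperiment()]).
#' @export
readExpression <- function(path, sampleSheet) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L)
    stop("expression table needs an id column plus at least one sample")
  ids <- as.character(tab[[1]])
  vals <- tab[, -1, drop = FALSE]
  num <- vapply(vals, is.numeric, logical(1))
  if (!all(num))
    stop("non-numeric expression values in column(s): ",
         paste(colnames(vals)[!num], collapse = ", "))
  m <- as.matrix(vals)
  rownames(m) <- ids
  sheet <- read.delim(sampleSheet, stringsAsFactors = FALSE)
  need <- c("sample", "tissue", "time_hour", "replicate")
  if (!all(need %in% colnames(sheet)))
    stop("sample sheet needs columns: ", paste(need, collapse = ", "))
  missing <- setdiff(colnames(m), sheet$sample)
  if (length(missing))
    stop("samples absent from sample sheet: ", paste(missing, collapse = ", "))
  sheet <- sheet[match(colnames(m), sheet$sample), ]
  fpkmExperiment(m, tissue = sheet$tissue,
                 time_hour = sheet$time_hour, replicate = sheet$replicate)
}

#' Write an expression matrix and its sample sheet
#'
#' @param se A \code{SummarizedExperiment} from [fpkmExperiment()].
#' @param path Output path for the expression TSV.
#' @param sampleSheet Output path for the sample sheet TSV (optional).
#' @return Invisibly, \code{path}.
#' @export
writeExpression <- function(se, path, sampleSheet = NULL) {
  m <- assay(se, "fpkm")
  out <- data.frame(transcript = rownames(m), m,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sampleSheet)) {
    cd <- as.data.frame(colData(se))
    sheet <- data.frame(sample = rownames(cd), tissue = cd$tissue,
                        time_hour = cd$time_hour, replicate = cd$replicate)
    write.table(sheet, sampleSheet, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

#' Average replicates into one column per condition
#'
#' Collapses an FPKM matrix to one column per (tissue, time point)
#' condition, taking the arithmetic mean over replicates. Non-negativity is
#' preserved. Conditions keep their first-appearance order.
#'
#' @param se A \code{SummarizedExperiment} with replicate metadata.
#' @return A \code{SummarizedExperiment} with one column per condition and
#'   \code{replicate = NA}.
#' @export
collapseReplicates <- function(se) {
  cd <- colData(se)
  key <- paste(cd$tissue, ifelse(is.na(cd$time_hour), "", cd$time_hour),
               sep = "@")
  ukey <- unique(key)
  m <- assay(se, "fpkm")
  cols <- lapply(ukey, function(k) {
    idx <- which(key == k)
    if (!length(idx)) stop("condition with zero replicates: ", k)
    rowMeans(m[, idx, drop = FALSE])
  })
  out <- do.call(cbind, cols)
  first <- match(ukey, key)
  cn <- ifelse(is.na(cd$time_hour[first]), cd$tissue[first],
               sprintf("%s_h%g", cd$tissue[first], cd$time_hour[first]))
  colnames(out) <- cn
  rownames(out) <- rownames(m)
  fpkmExperiment(out, tissue = cd$tissue[first],
                 time_hour = cd$time_hour[first])
}

#' Read a miRNA binding table
#'
#' Tab-delimited with columns \code{mirna}, \code{transcript}, \code{mode};
#' \code{mode} is \code{"perfect"} (cleavage-competent target site) or
#' \code{"mimic"} (imperfect, target-mimicry site). Duplicate
#' (mirna, transcript, mode) triples are rejected.
#'
#' @param path Path to the TSV.
#' @return A validated \code{data.frame}.
#' @export
readBindingTable <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  validateBindingTable(tab)
}

#' @rdname readBindingTable
#' @param bindings A data.frame with columns \code{mirna},
#'   \code{transcript}, \code{mode}.
#' @export
validateBindingTable <- function(bindings) {
  need <- c("mirna", "transcript", "mode")
  if (!all(need %in% colnames(bindings)))
    stop("binding table needs columns: ", paste(need, collapse = ", "))
  bindings <- bindings[, need, drop = FALSE]
  if (any(is.na(bindings$mode)) || !all(bindings$mode %in% c("perfect", "mimic")))
    stop("binding mode must be 'perfect' or 'mimic' for every record")
  if (anyDuplicated(bindings))
    stop("duplicate (mirna, transcript, mode) records in binding table")
  bindings
}

#' @rdname readBindingTable
#' @export
writeBindingTable <- function(bindings, path) {
  write.table(validateBindingTable(bindings), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert between 1-based inclusive and 0-based half-open intervals
#'
#' The package stores coordinates 1-based inclusive (GTF). These helpers
#' document the conversion to BED-style 0-based half-open intervals; the two
#' are mutual inverses.
#'
#' @param start,end 1-based inclusive coordinates.
#' @param start0,end0 0-based half-open coordinates.
#' @return A two-column data.frame of converted coordinates.
#' @export
toHalfOpen <- function(start, end)
  data.frame(start0 = start - 1L, end0 = end)

#' @rdname toHalfOpen
#' @export
fromHalfOpen <- function(start0, end0)
  data.frame(start = start0 + 1L, end = end0)
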