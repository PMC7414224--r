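#' Build a validated gene table
#'
#' Genes are kept in a plain data.frame with columns `gene_id`, `chrom`,
#' `start`, `end` (0-based, half-open), `strand` (`+`/`-`) and
#' `expression_rpkm` (reads per kilobase per million mapped reads, >= 0).
#'
#' @param gene_id character identifiers (unique).
#' @param chrom chromosome names.
#' @param start,end 0-based half-open coordinates.
#' @param strand `+` or `-` per gene.
#' @param expression_rpkm non-negative expression values; defaults to `NA`
#'   until an expression table is attached.
#' @param layout optional [genome_layout()] to validate coordinates against.
#' @return data.frame of class `gene_table`, ordered by (chrom, start, end,
#'   gene_id) with chrom order taken from `layout` when given.
#' @export
gene_table <- function(gene_id, chrom, start, end, strand,
                       expression_rpkm = NA_real_, layout = NULL) {
  expression_rpkm <- rep_len(as.numeric(expression_rpkm),
                             length(gene_id))
  df <- data.frame(gene_id = as.character(gene_id),
                   chrom = as.character(chrom),
                   start = as.numeric(start), end = as.numeric(end),
                   strand = as.character(strand),
                   expression_rpkm = as.numeric(expression_rpkm),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (anyDuplicated(df$gene_id)) stop("gene ids must be unique")
    bad <- which(!df$strand %in% c("+", "-"))
    if (length(bad)) stop("strand must be '+' or '-' at row ", bad[1])
    if (any(!is.na(df$expression_rpkm) & df$expression_rpkm < 0))
      stop("expression_rpkm must be >= 0")
    validate_intervals(df, layout, "gene")
    chrom_rank <- if (is.null(layout)) rank(sort(unique(df$chrom)))[df$chrom] else
      match(df$chrom, layout$chroms)
    df <- df[order(chrom_rank, df$start, df$end, df$gene_id), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("gene_table", "data.frame")
  df
}

#' Read a BED6/BED12 gene annotation
#'
#' Only the outer gene span is used; BED12 block columns are ignored. The
#' score column can optionally carry expression (RPKM) via
#' `score_is_expression`; otherwise expression is attached separately with
#' [attach_expression()].
#'
#' @param path BED file (>= 6 columns, tab- or space-separated).
#' @param layout optional [genome_layout()] for coordinate validation.
#' @param score_is_expression logical; interpret column 5 as RPKM.
#' @return a [gene_table()].
#' @export
read_gene_annotation <- function(path, layout = NULL,
                                 score_is_expression = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(gene_table(character(), character(), numeric(), numeric(),
                      character(), layout = layout))
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 6))
    stop("malformed BED row (fewer than 6 fields) at line ",
         which(nf < 6)[1])
  m <- do.call(rbind, lapply(fields, `[`, 1:6))
  start <- suppressWarnings(as.numeric(m[, 2]))
  end <- suppressWarnings(as.numeric(m[, 3]))
  score <- suppressWarnings(as.numeric(m[, 5]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) stop("non-numeric coordinates at line ", bad[1])
  bad <- which(!(start >= 0 & start < end))
  if (length(bad)) stop("start >= end (or negative start) at line ", bad[1])
  bad <- which(!m[, 6] %in% c("+", "-"))
  if (length(bad)) stop("strand must be '+' or '-' at line ", bad[1])
  gene_table(m[, 4], m[, 1], start, end, m[, 6],
             expression_rpkm = if (score_is_expression) score else NA_real_,
             layout = layout)
}

#' @rdname read_gene_annotation
#' @param genes a [gene_table()].
#' @export
write_gene_annotation <- function(genes, path) {
  score <- ifelse(is.na(genes$expression_rpkm), 0, genes$expression_rpkm)
  utils::write.table(
    data.frame(genes$chrom, format_num(genes$start), format_num(genes$end),
               genes$gene_id, format_num(score), genes$strand),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Attach an expression table to genes
#'
#' @param genes a [gene_table()].
#' @param path 2-column tab-separated file (gene id, count or RPKM).
#' @param header logical; whether the file has a header line.
#' @param as_counts if `TRUE` the second column is a read count and is
#'   converted to RPKM with [rpkm()] using the gene length and the summed
#'   counts as library size.
#' @return the gene table with `expression_rpkm` filled (0 for absent ids).
#' @export
attach_expression <- function(genes, path, header = FALSE, as_counts = FALSE) {
  dt <- data.table::fread(path, header = header, sep = "\t",
                          col.names = c("gene_id", "value"))
  v <- stats::setNames(as.numeric(dt$value), dt$gene_id)
  val <- unname(v[genes$gene_id])
  val[is.na(val)] <- 0
  if (as_counts)
    val <- rpkm(val, genes$end - genes$start, sum(dt$value))
  genes$expression_rpkm <- val
  genes
}

#' Anchor points (TSS / TTS) of genes
#'
#' Anchors are single 0-based base positions: for a `+` gene the TSS is
#' `start` and the TTS is `end - 1`; for a `-` gene the TSS is `end - 1` and
#' the TTS is `start`.
#'
#' @param genes a [gene_table()] (or any data.frame with `start`, `end`,
#'   `strand`).
#' @param kind `"TSS"` or `"TTS"`.
#' @return data.frame with columns `gene_id`, `chrom`, `kind`, `position`,
#'   `strand`, one row per gene in input order.
#' @examples
#' g <- gene_table("g1", "chr1", 1000, 5000, "+")
#' anchor_of(g, "TSS")$position  # 1000
#' anchor_of(g, "TTS")$position  # 4999
#' @export
anchor_of <- function(genes, kind = c("TSS", "TTS")) {
  kind <- match.arg(kind)
  plus <- genes$strand == "+"
  pos <- if (kind == "TSS") ifelse(plus, genes$start, genes$end - 1)
         else               ifelse(plus, genes$end - 1, genes$start)
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom, kind = kind,
             position = as.numeric(pos), strand = genes$strand,
             stringsAsFactors = FALSE)
}

#' Interval overlap query
#'
#' Reports every (query, subject) index pair with a nonzero overlap under
#' 0-based half-open semantics, ordered by query index then subject index.
#' Backed by IRanges per chromosome.
#'
#' @param query,subject data.frames with columns `chrom`, `start`, `end`.
#' @param layout optional [genome_layout()]; when given, intervals on unknown
#'   chromosomes are an error.
#' @return data.frame with integer columns `query` and `subject` (1-based row
#'   indices into the inputs).
#' @export
overlap_query <- function(query, subject, layout = NULL) {
  validate_intervals(query, layout, "query interval")
  validate_intervals(subject, layout, "subject interval")
  out <- list()
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    si <- which(subject$chrom == ch)
    if (!length(qi) || !length(si)) next
    # half-open [start, end) -> closed IRanges [start+1, end]
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(query$start[qi] + 1, query$end[qi]),
      IRanges::IRanges(subject$start[si] + 1, subject$end[si]))
    if (length(hits))
      out[[ch]] <- data.frame(query = qi[S4Vectors::queryHits(hits)],
                              subject = si[S4Vectors::subjectHits(hits)])
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(query = integer(), subject = integer())
  res <- res[order(res$query, res$subject), , drop = FALSE]
  rownames(res) <- NULL
  res
}
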