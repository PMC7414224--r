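#' Binned signal track
#'
#' Per-chromosome vectors of equal-width bin values. Bin `i` (1-based) covers
#' `[(i-1)*bin_size, i*bin_size)`; the last bin may be truncated by the
#' chromosome end. `flavor` records whether values are raw fragment counts or
#' a normalized ratio.
#'
#' @param layout a [genome_layout()].
#' @param bin_size bin width in bp.
#' @param values named list (one numeric vector per chromosome) or a single
#'   numeric vector for a one-chromosome layout; lengths must equal
#'   `ceiling(length / bin_size)`.
#' @param flavor `"raw"` (counts) or `"ratio"` (normalized).
#' @return object of class `signal_track`.
#' @export
signal_track <- function(layout, bin_size, values, flavor = c("raw", "ratio")) {
  flavor <- match.arg(flavor)
  stopifnot(inherits(layout, "genome_layout"), bin_size > 0)
  if (!is.list(values)) values <- stats::setNames(list(values), layout$chroms[1])
  nb <- n_bins(layout, bin_size)
  if (!setequal(names(values), layout$chroms))
    stop("values must name exactly the layout chromosomes")
  values <- values[layout$chroms]
  for (ch in layout$chroms) {
    if (length(values[[ch]]) != nb[[ch]])
      stop("chromosome ", ch, ": expected ", nb[[ch]], " bins, got ",
           length(values[[ch]]))
    if (any(!is.finite(values[[ch]])))
      stop("chromosome ", ch, ": non-finite bin values")
  }
  structure(list(layout = layout, bin_size = bin_size, values = values,
                 flavor = flavor), class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat("signal_track (", x$flavor, "): ", length(x$values), " chromosome(s), ",
      format_num(x$bin_size), " bp bins, ",
      sum(lengths(x$values)), " bins\n", sep = "")
  invisible(x)
}

track_total <- function(track) sum(vapply(track$values, sum, numeric(1)))

same_binning <- function(a, b) {
  a$bin_size == b$bin_size &&
    identical(a$layout$chroms, b$layout$chroms) &&
    identical(unname(a$layout$lengths), unname(b$layout$lengths))
}

#' Read / write bedGraph
#'
#' Four-column tab-separated `chrom start end value` with 0-based half-open
#' records. Records must be sorted and non-overlapping per chromosome (or
#' pass `sort = TRUE`). Rows are projected onto bins of `bin_size`; for
#' bin-aligned input the read-back is bit-exact.
#'
#' @param path file path.
#' @param layout a [genome_layout()].
#' @param bin_size bin width of the returned track.
#' @param flavor value flavor of the returned track.
#' @param sort sort records instead of erroring when out of order.
#' @return a [signal_track()] (bins not covered by any record are 0).
#' @export
read_bedgraph <- function(path, layout, bin_size, flavor = "ratio",
                          sort = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "value"))
  validate_intervals(dt, layout, "bedGraph record")
  nb <- n_bins(layout, bin_size)
  vals <- lapply(nb, numeric)
  for (ch in unique(dt$chrom)) {
    d <- dt[dt$chrom == ch, ]
    o <- order(d$start)
    if (!identical(o, seq_len(nrow(d)))) {
      if (sort) d <- d[o, ] else stop("unsorted bedGraph records on ", ch)
    }
    if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)]))
      stop("overlapping bedGraph records on ", ch)
    v <- vals[[ch]]
    for (i in seq_len(nrow(d))) {
      b0 <- floor(d$start[i] / bin_size) + 1
      b1 <- ceiling(d$end[i] / bin_size)
      v[b0:b1] <- d$value[i]
    }
    vals[[ch]] <- v
  }
  signal_track(layout, bin_size, vals, flavor = flavor)
}

#' @rdname read_bedgraph
#' @param track a [signal_track()].
#' @export
write_bedgraph <- function(track, path) {
  rows <- lapply(track$layout$chroms, function(ch) {
    v <- track$values[[ch]]
    L <- chrom_length(track$layout, ch)
    starts <- (seq_along(v) - 1) * track$bin_size
    ends <- pmin(starts + track$bin_size, L)
    # run-length merge of equal adjacent values keeps files small
    r <- rle(v)
    idx <- cumsum(r$lengths)
    first <- c(1, idx[-length(idx)] + 1)
    data.frame(chrom = ch, start = format_num(starts[first]),
               end = format_num(ends[idx]), value = format_num(r$values))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Reads per kilobase per million mapped reads
#'
#' `RPKM = count * 1e9 / (length * library_size)`.
#'
#' @param count reads in the feature (vectorized).
#' @param length_bp feature length in bp (> 0).
#' @param library_size total mapped reads (> 0).
#' @return numeric RPKM values.
#' @examples
#' rpkm(10, 1000, 1e6)  # 10
#' @export
rpkm <- function(count, length_bp, library_size) {
  if (any(length_bp <= 0)) stop("feature length must be > 0")
  if (any(library_size <= 0)) stop("library size must be > 0")
  if (any(count < 0)) stop("count must be >= 0")
  count * 1e9 / (length_bp * library_size)
}

#' Scale a raw track to a target total (reads-per-million by default)
#'
#' @param track a raw-count [signal_track()].
#' @param target_total total signal after scaling.
#' @return a ratio-flavored track with the same shape.
#' @export
scale_track <- function(track, target_total = 1e6) {
  tot <- track_total(track)
  f <- if (tot > 0) target_total / tot else 0
  signal_track(track$layout, track$bin_size,
               lapply(track$values, function(v) v * f), flavor = "ratio")
}

#' IP over input ratio track
#'
#' Both tracks are first scaled to a common total (library-size scaling),
#' then the per-bin ratio `(ip + pseudocount) / (input + pseudocount)` is
#' returned.
#'
#' @param ip,input [signal_track()]s on the same layout and binning.
#' @param pseudocount strictly positive stabilizer.
#' @param scale scale both tracks to reads-per-million first (default TRUE;
#'   disable when the tracks are already normalized).
#' @return a ratio [signal_track()].
#' @export
ip_over_input <- function(ip, input, pseudocount = 1, scale = TRUE) {
  if (!same_binning(ip, input)) stop("ip and input binning mismatch")
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  if (scale) {
    ip <- scale_track(ip); input <- scale_track(input)
  }
  vals <- stats::setNames(lapply(ip$layout$chroms, function(ch)
    (ip$values[[ch]] + pseudocount) / (input$values[[ch]] + pseudocount)),
    ip$layout$chroms)
  signal_track(ip$layout, ip$bin_size, vals, flavor = "ratio")
}

#' Active genes (RPKM > 0)
#'
#' @param genes a [gene_table()] with expression set.
#' @return the subset with `expression_rpkm > 0`.
#' @export
filter_active <- function(genes) {
  if (any(is.na(genes$expression_rpkm)))
    stop("expression must be set on all genes before filtering")
  genes[genes$expression_rpkm > 0, , drop = FALSE]
}

#' Expression quintiles
#'
#' Genes are sorted by expression (descending, ties broken by gene id) and
#' split into five groups: quintile 1 holds the most expressed genes.
#' Groups 1-4 each take `floor(N/5)` genes; group 5 takes the remainder, so
#' the printed common group size is `floor(N/5)` (35,251 genes give 7,050).
#'
#' @param genes a [gene_table()] with >= 5 genes.
#' @return list with `assignment` (named integer vector, gene id ->
#'   quintile 1-5) and `sizes` (integer vector of the five group sizes).
#' @export
expression_quintiles <- function(genes) {
  n <- nrow(genes)
  if (n < 5) stop("need at least 5 genes for quintiles")
  ord <- order(-genes$expression_rpkm, genes$gene_id)
  base <- n %/% 5L
  sizes <- c(rep(base, 4L), n - 4L * base)
  q <- rep.int(1:5, sizes)
  assignment <- integer(n)
  assignment[ord] <- q
  list(assignment = stats::setNames(assignment, genes$gene_id),
       sizes = sizes)
}
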