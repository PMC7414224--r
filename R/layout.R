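#' Genome layout
#'
#' A genome layout is the ordered set of chromosome names and their lengths
#' in base pairs. Every track, gene table and interval set in the package is
#' validated against a layout when one is attached.
#'
#' @param chroms character vector of unique chromosome names, in the order
#'   used for all deterministic sorting.
#' @param lengths numeric vector of chromosome lengths (bp), parallel to
#'   `chroms`; all strictly positive.
#' @return An object of class `genome_layout` with fields `chroms` and
#'   `lengths` (named by chromosome).
#' @examples
#' genome_layout("chrS", 2e7)
#' @export
genome_layout <- function(chroms, lengths) {
  chroms <- as.character(chroms)
  lengths <- as.numeric(lengths)
  if (length(chroms) != length(lengths))
    stop("chroms and lengths must have equal length")
  if (anyDuplicated(chroms)) stop("chromosome names must be unique")
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("chromosome lengths must be finite and > 0")
  names(lengths) <- chroms
  structure(list(chroms = chroms, lengths = lengths), class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("genome_layout:", length(x$chroms), "chromosome(s),",
      format(sum(x$lengths), big.mark = ","), "bp total\n")
  invisible(x)
}

#' Read / write a chrom-sizes file
#'
#' Two-column tab-separated text (`chrom<TAB>length`), the UCSC convention.
#'
#' @param path file path.
#' @return `read_chrom_sizes` returns a [genome_layout()].
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "length"))
  genome_layout(dt$chrom, dt$length)
}

#' @rdname read_chrom_sizes
#' @param layout a [genome_layout()].
#' @export
write_chrom_sizes <- function(layout, path) {
  stopifnot(inherits(layout, "genome_layout"))
  utils::write.table(
    data.frame(chrom = layout$chroms,
               length = format_num(layout$lengths)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# full-precision, locale-stable number formatting used by all writers
format_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (v == floor(v) && abs(v) < 2^53) sprintf("%.0f", v) else sprintf("%.17g", v)
  }, character(1))
}

chrom_length <- function(layout, chrom) {
  if (!chrom %in% layout$chroms) stop("unknown chromosome: ", chrom)
  unname(layout$lengths[[chrom]])
}

n_bins <- function(layout, bin_size) {
  stats::setNames(as.integer(ceiling(layout$lengths / bin_size)), layout$chroms)
}

# validate a chrom/start/end data.frame against a layout (0-based half-open)
validate_intervals <- function(df, layout = NULL, what = "interval") {
  if (nrow(df) == 0) return(invisible(df))
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad))
    stop(what, " invariant 0 <= start < end violated at row ", bad[1])
  if (!is.null(layout)) {
    unknown <- setdiff(unique(df$chrom), layout$chroms)
    if (length(unknown))
      stop(what, " on unknown chromosome: ", unknown[1])
    over <- which(df$end > layout$lengths[df$chrom])
    if (length(over))
      stop(what, " extends past chromosome end at row ", over[1])
  }
  invisible(df)
}
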