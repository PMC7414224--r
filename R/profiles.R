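#' Mean signal in a fixed window around gene anchors
#'
#' Per gene, the mean track value over `[position - half_width,
#' position + half_width)`, clipped at chromosome ends. This is the "TTS
#' +/- 2 kb" quantification used throughout the break-site analyses.
#'
#' @param track a [signal_track()].
#' @param anchors data.frame from [anchor_of()] (or any frame with `chrom`,
#'   `position`).
#' @param half_width window half width in bp.
#' @return numeric vector, one mean per anchor row.
#' @export
window_quantify <- function(track, anchors, half_width = 2000) {
  out <- rep(NA_real_, nrow(anchors))
  b <- track$bin_size
  for (ch in unique(anchors$chrom)) {
    sel <- which(anchors$chrom == ch)
    v <- track$values[[ch]]
    lo <- pmax(floor((anchors$position[sel] - half_width) / b) + 1, 1)
    hi <- pmin(ceiling((anchors$position[sel] + half_width) / b), length(v))
    cs <- cumsum(c(0, v))
    out[sel] <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }
  out
}

#' Metagene profile with SEM
#'
#' Builds the per-gene signal matrix either in `anchor` mode (a fixed window
#' centered on the TSS or TTS) or in `scaled` mode (the TSS..TTS body mean-
#' pooled into `body_bins` columns, flanked by `flank` bp on each side).
#' Rows of `-` strand genes are reversed so every row reads 5' to 3'.
#'
#' @param track a [signal_track()].
#' @param genes a [gene_table()].
#' @param mode `"scaled"` or `"anchor"`.
#' @param anchor `"TSS"` or `"TTS"` (anchor mode only).
#' @param flank flanking extent in bp (default 10,000).
#' @param body_bins columns for the rescaled gene body (scaled mode).
#' @return list of class `meta_profile`: `matrix` (genes x columns,
#'   rownames = gene ids), `mean`, `sem` (sd / sqrt(n) per column),
#'   `columns` (bp offsets or schema labels), `skipped` (genes shorter than
#'   one bin, dropped with a count).
#' @export
meta_profile <- function(track, genes, mode = c("anchor", "scaled"),
                         anchor = "TTS", flank = 10000, body_bins = 100) {
  mode <- match.arg(mode)
  if (!nrow(genes)) stop("no genes supplied")
  b <- track$bin_size
  flank_bins <- as.integer(round(flank / b))
  rows <- list(); skipped <- 0L
  for (i in seq_len(nrow(genes))) {
    ch <- genes$chrom[i]; v <- track$values[[ch]]
    gb0 <- floor(genes$start[i] / b) + 1
    gb1 <- ceiling(genes$end[i] / b)
    if (gb1 < gb0) { skipped <- skipped + 1L; next }
    grab <- function(lo, hi) { # bins outside the chromosome read as NA
      idx <- lo:hi
      out <- rep(NA_real_, length(idx))
      ok <- idx >= 1 & idx <= length(v)
      out[ok] <- v[idx[ok]]
      out
    }
    if (mode == "anchor") {
      a <- anchor_of(genes[i, , drop = FALSE], anchor)
      ab <- floor(a$position / b) + 1
      row <- grab(ab - flank_bins, ab + flank_bins - 1L)
    } else {
      body <- grab(gb0, gb1)
      row <- c(grab(gb0 - flank_bins, gb0 - 1L),
               pool_bins(body, body_bins),
               grab(gb1 + 1L, gb1 + flank_bins))
    }
    if (genes$strand[i] == "-") row <- rev(row)
    rows[[length(rows) + 1L]] <- row
    names(rows)[length(rows)] <- genes$gene_id[i]
  }
  if (!length(rows)) stop("all genes were skipped")
  mat <- do.call(rbind, rows)
  cols <- if (mode == "anchor")
    ((seq_len(2L * flank_bins) - flank_bins) - 0.5) * b
  else seq_len(ncol(mat))
  mu <- colMeans(mat, na.rm = TRUE)
  n_ok <- colSums(!is.na(mat))
  sem <- apply(mat, 2, stats::sd, na.rm = TRUE) / sqrt(pmax(n_ok, 1))
  sem[n_ok < 2] <- 0
  structure(list(matrix = mat, mean = mu, sem = sem, columns = cols,
                 mode = mode, skipped = skipped), class = "meta_profile")
}

# mean-pool (or linearly interpolate when shorter) a vector into k bins
pool_bins <- function(x, k) {
  m <- length(x)
  if (m == k) return(x)
  if (m > k) {
    grp <- ceiling(seq_len(m) / m * k)
    as.numeric(tapply(x, grp, mean))
  } else {
    stats::approx(seq(0, 1, length.out = m), x,
                  xout = seq(0, 1, length.out = k))$y
  }
}

#' Quintile-stratified, DRIP-sorted anchor heatmaps
#'
#' For each track, the per-gene signal in a window centered on the TTS; genes
#' are grouped by expression quintile and, within each quintile, ordered by
#' decreasing mean signal of the sort track (DRIP by convention). The same
#' row order is applied to every track so the matrices are directly
#' comparable.
#'
#' @param tracks named list of [signal_track()]s; must contain `sort_track`.
#' @param genes a [gene_table()].
#' @param quintiles an [expression_quintiles()] result on the same genes.
#' @param half_width window half width in bp (default 10,000).
#' @param sort_track name of the track used for within-quintile ordering.
#' @return list: `matrices` (named list of gene x bin matrices, common row
#'   order), `order` (gene ids), `quintile` (integer per row), `sizes`.
#' @export
tts_heatmap <- function(tracks, genes, quintiles, half_width = 10000,
                        sort_track = "DRIP") {
  if (!sort_track %in% names(tracks))
    stop("sort track '", sort_track, "' not in tracks")
  if (!all(genes$gene_id %in% names(quintiles$assignment)))
    stop("quintile assignment does not cover the gene set")
  q <- unname(quintiles$assignment[genes$gene_id])
  prof <- lapply(tracks, function(tr)
    meta_profile(tr, genes, mode = "anchor", anchor = "TTS",
                 flank = half_width)$matrix)
  key <- rowMeans(prof[[sort_track]], na.rm = TRUE)
  ord <- order(q, -key, genes$gene_id)
  list(matrices = lapply(prof, function(m) m[ord, , drop = FALSE]),
       order = genes$gene_id[ord], quintile = q[ord],
       sizes = as.integer(table(factor(q, levels = 1:5))))
}
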