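#' Stranded Okazaki-fragment bin counts
#'
#' Per-bin Watson (W) and Crick (C) fragment counts from OK-seq. Crick-mapping
#' Okazaki fragments indicate rightward-moving forks, so
#' `RFD = (C - W) / (C + W)` with +1 meaning purely rightward replication.
#'
#' @param layout a [genome_layout()].
#' @param bin_size bin width in bp.
#' @param watson,crick named lists of non-negative integer vectors per
#'   chromosome (or plain vectors for a one-chromosome layout).
#' @return object of class `stranded_bin_counts`.
#' @export
stranded_bin_counts <- function(layout, bin_size, watson, crick) {
  as_list <- function(v) if (is.list(v)) v else
    stats::setNames(list(v), layout$chroms[1])
  watson <- as_list(watson); crick <- as_list(crick)
  nb <- n_bins(layout, bin_size)
  for (ch in layout$chroms) {
    for (v in list(watson[[ch]], crick[[ch]])) {
      if (length(v) != nb[[ch]]) stop("bin count mismatch on ", ch)
      if (any(v < 0) || any(v != floor(v)))
        stop("counts must be non-negative integers on ", ch)
    }
  }
  structure(list(layout = layout, bin_size = bin_size,
                 watson = watson[layout$chroms], crick = crick[layout$chroms]),
            class = "stranded_bin_counts")
}

#' Read / write OK-seq bin counts
#'
#' Five-column tab-separated text: `chrom start end watson crick`,
#' 0-based half-open, bin-aligned.
#'
#' @param path file path.
#' @param layout a [genome_layout()].
#' @param bin_size bin width in bp.
#' @return a [stranded_bin_counts()].
#' @export
read_okseq <- function(path, layout, bin_size) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
    col.names = c("chrom", "start", "end", "watson", "crick"))
  validate_intervals(dt, layout, "okseq record")
  nb <- n_bins(layout, bin_size)
  W <- lapply(nb, numeric); C <- lapply(nb, numeric)
  idx <- floor(dt$start / bin_size) + 1
  for (ch in unique(dt$chrom)) {
    sel <- dt$chrom == ch
    W[[ch]][idx[sel]] <- dt$watson[sel]
    C[[ch]][idx[sel]] <- dt$crick[sel]
  }
  stranded_bin_counts(layout, bin_size, W, C)
}

#' @rdname read_okseq
#' @param counts a [stranded_bin_counts()].
#' @export
write_okseq <- function(counts, path) {
  rows <- lapply(counts$layout$chroms, function(ch) {
    v <- counts$watson[[ch]]
    starts <- (seq_along(v) - 1) * counts$bin_size
    data.frame(chrom = ch, start = format_num(starts),
               end = format_num(pmin(starts + counts$bin_size,
                                     chrom_length(counts$layout, ch))),
               watson = format_num(v),
               crick = format_num(counts$crick[[ch]]))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Parameters for fork-direction analysis
#'
#' @param theta orientation threshold in (0, 1): an anchor is called head-on
#'   (HO) or codirectional (CD) only when the signed codirectional RFD clears
#'   this magnitude; below it the call is `ambiguous`.
#' @param min_coverage minimum `W + C` fragments per bin for a valid RFD
#'   value; lower-coverage bins are masked (NA).
#' @param smooth_bins width (bins) of the centered moving average applied
#'   before initiation-zone detection. The default (5 bins = 5 kb at the
#'   default binning) is chosen so the window stays well below the typical
#'   inter-origin distance; wider windows smear adjacent ascending strand
#'   switches into each other and miss origins.
#' @return list of class `conflict_params`.
#' @export
conflict_params <- function(theta = 0.25, min_coverage = 30,
                            smooth_bins = 5) {
  if (theta <= 0 || theta >= 1) stop("theta must be in (0, 1)")
  if (min_coverage < 0) stop("min_coverage must be >= 0")
  structure(list(theta = theta, min_coverage = min_coverage,
                 smooth_bins = as.integer(smooth_bins)),
            class = "conflict_params")
}

moving_average <- function(v, w) {
  if (w <= 1) return(v)
  half <- (w - 1) %/% 2
  n <- length(v)
  ok <- !is.na(v)
  x <- ifelse(ok, v, 0)
  cs <- cumsum(c(0, x)); cn <- cumsum(c(0, as.numeric(ok)))
  lo <- pmax(seq_len(n) - half, 1); hi <- pmin(seq_len(n) + half, n)
  num <- cs[hi + 1] - cs[lo]
  den <- cn[hi + 1] - cn[lo]
  out <- ifelse(den > 0, num / den, NA_real_)
  out[!ok] <- NA_real_
  out
}

#' Replication fork direction from Okazaki counts
#'
#' Per valid bin, `RFD = (C - W) / (C + W)` in `[-1, 1]`; +1 denotes purely
#' rightward fork movement. Bins with `C + W < min_coverage` are masked (NA).
#'
#' @param counts a [stranded_bin_counts()].
#' @param params a [conflict_params()].
#' @param smooth apply the centered moving average of `params$smooth_bins`
#'   (default `FALSE`; zone detection smooths internally).
#' @return a [signal_track()] of class `c("rfd_track", "signal_track")` with
#'   NA on masked bins.
#' @examples
#' # (C = 30, W = 10) -> (30 - 10) / 40 = 0.5
#' @export
compute_rfd <- function(counts, params = conflict_params(), smooth = FALSE) {
  vals <- stats::setNames(lapply(counts$layout$chroms, function(ch) {
    W <- counts$watson[[ch]]; C <- counts$crick[[ch]]
    tot <- W + C
    r <- ifelse(tot >= max(params$min_coverage, 1), (C - W) / tot, NA_real_)
    if (smooth) r <- moving_average(r, params$smooth_bins)
    r
  }), counts$layout$chroms)
  structure(list(layout = counts$layout, bin_size = counts$bin_size,
                 values = vals, flavor = "ratio"),
            class = c("rfd_track", "signal_track"))
}

#' Detect replication initiation zones
#'
#' After smoothing, an initiation zone is a direct transit of the RFD profile
#' from at most `-theta` up to at least `+theta` (an ascending strand switch,
#' the OK-seq signature of preferential origin firing). The zone runs from
#' the last bin at or below `-theta` to the first bin at or above `+theta`;
#' its center is the midpoint and its efficiency proxy is half the RFD rise
#' across it.
#'
#' @param rfd an RFD [signal_track()] from [compute_rfd()].
#' @param params a [conflict_params()] (`theta`, `smooth_bins`).
#' @return data.frame with `chrom`, `start`, `end` (bp, half-open), `center`
#'   (bp), `efficiency` in (0, 1], sorted by position.
#' @export
detect_initiation_zones <- function(rfd, params = conflict_params()) {
  theta <- params$theta
  zones <- lapply(rfd$layout$chroms, function(ch) {
    v <- moving_average(rfd$values[[ch]], params$smooth_bins)
    n <- length(v)
    res <- list()
    armed <- FALSE; left <- NA_integer_
    for (i in seq_len(n)) {
      x <- v[i]
      if (is.na(x)) next
      if (x <= -theta) { armed <- TRUE; left <- i }
      else if (armed && x >= theta) {
        res[[length(res) + 1]] <- c(left, i, v[left], x)
        armed <- FALSE
      }
    }
    if (!length(res)) return(NULL)
    m <- do.call(rbind, res)
    b <- rfd$bin_size
    start <- (m[, 1] - 1) * b
    end <- pmin(m[, 2] * b, chrom_length(rfd$layout, ch))
    data.frame(chrom = ch, start = start, end = end,
               center = (start + end) / 2,
               efficiency = pmin((m[, 4] - m[, 3]) / 2, 1))
  })
  zones <- do.call(rbind, zones[!vapply(zones, is.null, logical(1))])
  if (is.null(zones))
    zones <- data.frame(chrom = character(), start = numeric(),
                        end = numeric(), center = numeric(),
                        efficiency = numeric())
  rownames(zones) <- NULL
  zones
}

#' Head-on / codirectional orientation at gene anchors
#'
#' The signed codirectional RFD at an anchor is `s = strand_sign * RFD`,
#' where `strand_sign` is +1 for a `+` gene and -1 for a `-` gene. Forks
#' moving with transcription give `s > 0` (codirectional, CD); forks moving
#' against it give `s < 0` (head-on, HO). Calls require `|s| >= theta`;
#' masked or weak bins are `ambiguous`.
#'
#' @param genes a [gene_table()].
#' @param kind `"TSS"` or `"TTS"` anchor.
#' @param rfd an RFD track from [compute_rfd()].
#' @param params a [conflict_params()].
#' @param window_bins average RFD over this many bins centered on the anchor
#'   (default 1 = the anchor bin only).
#' @return data.frame with `gene_id`, `orientation` in {HO, CD, ambiguous},
#'   `signed_rfd`, and `masked` (TRUE when the anchor bin carried no value).
#' @export
orientation_at <- function(genes, kind, rfd, params = conflict_params(),
                           window_bins = 1L) {
  anchors <- anchor_of(genes, kind)
  n <- nrow(anchors)
  s <- rep(NA_real_, n)
  for (ch in unique(anchors$chrom)) {
    sel <- which(anchors$chrom == ch)
    v <- rfd$values[[ch]]
    bin <- floor(anchors$position[sel] / rfd$bin_size) + 1
    if (window_bins > 1) {
      half <- (window_bins - 1) %/% 2
      val <- vapply(bin, function(b) {
        w <- v[max(1, b - half):min(length(v), b + half)]
        if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
      }, numeric(1))
    } else val <- v[bin]
    s[sel] <- ifelse(anchors$strand[sel] == "+", 1, -1) * val
  }
  orientation <- ifelse(is.na(s), "ambiguous",
                 ifelse(s >= params$theta, "CD",
                 ifelse(s <= -params$theta, "HO", "ambiguous")))
  data.frame(gene_id = anchors$gene_id, orientation = orientation,
             signed_rfd = s, masked = is.na(s), stringsAsFactors = FALSE)
}

#' Distance from each TTS to the nearest downstream initiation zone
#'
#' "Downstream" means past the TTS in the direction of transcription
#' (rightward for `+` genes, leftward for `-` genes). Distances are measured
#' to zone centers on the same chromosome; `NA` when no such zone exists.
#'
#' @param genes a [gene_table()].
#' @param zones data.frame from [detect_initiation_zones()].
#' @return numeric vector (bp), one value per gene in input order.
#' @export
distance_to_downstream_origin <- function(genes, zones) {
  tts <- anchor_of(genes, "TTS")
  out <- rep(NA_real_, nrow(tts))
  for (ch in unique(tts$chrom)) {
    centers <- sort(zones$center[zones$chrom == ch])
    if (!length(centers)) next
    sel <- which(tts$chrom == ch)
    for (i in sel) {
      p <- tts$position[i]
      d <- if (tts$strand[i] == "+") centers[centers > p] - p
           else p - centers[centers < p]
      if (length(d)) out[i] <- min(d)
    }
  }
  out
}

#' @rdname detect_initiation_zones
#' @param zones data.frame of zones.
#' @param path BED6 output (name = zone index, score = efficiency proxy).
#' @export
write_zones_bed <- function(zones, path) {
  utils::write.table(
    data.frame(zones$chrom, format_num(zones$start), format_num(zones$end),
               paste0("IZ_", seq_len(nrow(zones))),
               format_num(zones$efficiency), "."),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
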