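#' Peak-calling configuration
#'
#' Simplified MACS-style caller: the per-bin background rate lambda is the
#' maximum of the genome-wide input mean and a local (10 kb by default) input
#' mean, scaled to the IP library size; enrichment p-values are Poisson upper
#' tails, adjusted genome-wide by Benjamini-Hochberg.
#'
#' @param q_threshold BH q-value cutoff (default 0.05).
#' @param local_bp width of the local background window in bp.
#' @param merge_gap maximum gap (bins) bridged when merging significant bins.
#' @param min_width minimum peak width in bins.
#' @return list of class `peak_call_config`.
#' @export
peak_call_config <- function(q_threshold = 0.05, local_bp = 10000,
                             merge_gap = 1L, min_width = 2L) {
  if (q_threshold <= 0 || q_threshold >= 1) stop("q_threshold must be in (0,1)")
  structure(list(q_threshold = q_threshold, local_bp = local_bp,
                 merge_gap = as.integer(merge_gap),
                 min_width = as.integer(min_width)),
            class = "peak_call_config")
}

#' Call enrichment peaks with a Poisson local-background model
#'
#' @param ip,input raw-count [signal_track()]s on identical binning.
#' @param cfg a [peak_call_config()].
#' @return data.frame of peaks: `chrom`, `start`, `end` (bp, half-open),
#'   `summit` (bp, center of the max-IP bin, leftmost on ties), `enrichment`
#'   (IP / lambda at the summit), `q_value` (minimum over member bins),
#'   sorted by position. Empty (not an error) when nothing is enriched.
#' @export
call_peaks <- function(ip, input, cfg = peak_call_config()) {
  if (!same_binning(ip, input)) stop("ip/input binning mismatch")
  ip_tot <- track_total(ip); in_tot <- track_total(input)
  if (ip_tot == 0 && in_tot == 0)
    return(empty_peaks())
  # background scaling: lower-quartile bin ratio (SES-style) rather than the
  # total-count ratio, so enrichment itself cannot inflate the background
  # rate when a large fraction of the genome carries signal
  q_ip <- stats::quantile(unlist(ip$values, use.names = FALSE), 0.25)
  q_in <- stats::quantile(unlist(input$values, use.names = FALSE), 0.25)
  ratio <- if (q_ip > 0 && q_in > 0) unname(q_ip / q_in)
           else if (in_tot > 0) ip_tot / in_tot else 1
  global_mean <- mean(unlist(input$values, use.names = FALSE))
  local_bins <- max(1L, as.integer(round(cfg$local_bp / ip$bin_size)))
  # genome-wide BH: gather all p-values first
  per_chrom <- lapply(ip$layout$chroms, function(ch) {
    x <- ip$values[[ch]]
    bg <- input$values[[ch]]
    lambda <- pmax(global_mean, moving_average(bg, local_bins)) * ratio
    lambda <- pmax(lambda, 1e-9)
    p <- stats::ppois(x - 1, lambda, lower.tail = FALSE)
    list(x = x, lambda = lambda, p = p)
  })
  names(per_chrom) <- ip$layout$chroms
  pall <- unlist(lapply(per_chrom, `[[`, "p"), use.names = FALSE)
  qall <- stats::p.adjust(pall, method = "BH")
  offs <- cumsum(c(0, vapply(per_chrom, function(z) length(z$p), numeric(1))))
  res <- list()
  for (k in seq_along(per_chrom)) {
    ch <- ip$layout$chroms[k]
    z <- per_chrom[[k]]
    q <- qall[(offs[k] + 1):offs[k + 1]]
    sig <- which(q <= cfg$q_threshold)
    if (!length(sig)) next
    # merge significant bins across gaps <= merge_gap
    brk <- which(diff(sig) > cfg$merge_gap + 1L)
    starts <- sig[c(1, brk + 1)]; ends <- sig[c(brk, length(sig))]
    keep <- (ends - starts + 1L) >= cfg$min_width
    if (!any(keep)) next
    starts <- starts[keep]; ends <- ends[keep]
    b <- ip$bin_size
    res[[ch]] <- do.call(rbind, lapply(seq_along(starts), function(i) {
      bins <- starts[i]:ends[i]
      smt <- bins[which.max(z$x[bins])]
      data.frame(chrom = ch, start = (starts[i] - 1) * b,
                 end = min(ends[i] * b, chrom_length(ip$layout, ch)),
                 summit = (smt - 0.5) * b,
                 enrichment = z$x[smt] / z$lambda[smt],
                 q_value = min(q[bins]))
    }))
  }
  if (!length(res)) return(empty_peaks())
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

empty_peaks <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             summit = numeric(), enrichment = numeric(), q_value = numeric())
}

#' Replicate-reproducible peaks
#'
#' A simplified stand-in for IDR: a peak from the first replicate is kept
#' when every other replicate (2 to 5 supported) has a peak matching it with
#' at least 50% reciprocal overlap; the consensus interval is the
#' intersection of the matched peaks.
#'
#' @param peak_sets list of >= 2 peak data.frames (as from [call_peaks()]).
#' @param min_reciprocal minimum reciprocal overlap fraction.
#' @return consensus peak data.frame (columns of replicate 1, intersected
#'   coordinates).
#' @export
reproducible_peaks <- function(peak_sets, min_reciprocal = 0.5) {
  if (!is.list(peak_sets) || length(peak_sets) < 2)
    stop("need at least 2 replicate peak sets")
  cons <- peak_sets[[1]]
  for (j in 2:length(peak_sets)) {
    other <- peak_sets[[j]]
    if (!nrow(cons) || !nrow(other)) return(empty_peaks())
    hits <- overlap_query(cons, other)
    if (!nrow(hits)) return(empty_peaks())
    ov_start <- pmax(cons$start[hits$query], other$start[hits$subject])
    ov_end <- pmin(cons$end[hits$query], other$end[hits$subject])
    ov <- ov_end - ov_start
    wq <- cons$end[hits$query] - cons$start[hits$query]
    ws <- other$end[hits$subject] - other$start[hits$subject]
    good <- ov >= min_reciprocal * wq & ov >= min_reciprocal * ws
    if (!any(good)) return(empty_peaks())
    hits <- hits[good, ]; ov_start <- ov_start[good]; ov_end <- ov_end[good]
    # best match (largest overlap) per replicate-1 peak
    best <- tapply(seq_len(nrow(hits)), hits$query, function(i)
      i[which.max(ov_end[i] - ov_start[i])])
    best <- unlist(best)
    cons <- cons[hits$query[best], , drop = FALSE]
    cons$start <- ov_start[best]; cons$end <- ov_end[best]
    cons$summit <- pmin(pmax(cons$summit, cons$start), cons$end - 1)
    rownames(cons) <- NULL
  }
  cons
}

#' Annotate peaks by genomic feature category
#'
#' Each peak is classified by its summit with priority
#' TSS region > TTS region > gene body > intergenic, where the TSS region
#' spans 3 kb upstream of the TSS through a fixed 5'-UTR proxy into the
#' gene, and the TTS region spans a 3'-UTR proxy before the TTS through 3 kb
#' past it. A random-placement baseline (the genomic bp fraction of each
#' category under the same priority) is reported alongside.
#'
#' @param peaks peak data.frame with a `summit` column.
#' @param genes a [gene_table()].
#' @param layout a [genome_layout()] (for the random baseline).
#' @param upstream,downstream flank sizes in bp (default 3,000).
#' @param utr_proxy bp extent standing in for the annotated UTRs (500).
#' @return list with `categories` (per-peak factor), `fractions` and
#'   `baseline` (named numeric, each summing to 1).
#' @export
annotate_peaks <- function(peaks, genes, layout, upstream = 3000,
                           downstream = 3000, utr_proxy = 500) {
  cats <- c("TSS_region", "TTS_region", "gene_body", "intergenic")
  region_tables <- function() {
    plus <- genes$strand == "+"
    tss <- anchor_of(genes, "TSS"); tts <- anchor_of(genes, "TTS")
    tss_start <- ifelse(plus, tss$position - upstream, tss$position - utr_proxy + 1)
    tss_end <- ifelse(plus, tss$position + utr_proxy, tss$position + upstream + 1)
    tts_start <- ifelse(plus, tts$position - utr_proxy + 1, tts$position - downstream)
    tts_end <- ifelse(plus, tts$position + downstream + 1, tts$position + utr_proxy)
    clamp <- function(df) {
      df$start <- pmax(df$start, 0)
      df$end <- pmin(df$end, layout$lengths[df$chrom])
      df[df$start < df$end, , drop = FALSE]
    }
    list(TSS_region = clamp(data.frame(chrom = genes$chrom, start = tss_start,
                                       end = tss_end)),
         TTS_region = clamp(data.frame(chrom = genes$chrom, start = tts_start,
                                       end = tts_end)),
         gene_body = clamp(data.frame(chrom = genes$chrom, start = genes$start,
                                      end = genes$end)))
  }
  regs <- region_tables()
  summits <- data.frame(chrom = peaks$chrom, start = peaks$summit,
                        end = peaks$summit + 1)
  cat_of <- rep("intergenic", nrow(peaks))
  for (nm in c("gene_body", "TTS_region", "TSS_region")) { # ascending priority
    if (!nrow(peaks)) break
    hits <- overlap_query(summits, regs[[nm]])
    cat_of[unique(hits$query)] <- nm
  }
  categories <- factor(cat_of, levels = cats)
  fractions <- if (nrow(peaks)) as.numeric(table(categories)) / nrow(peaks)
               else rep(NA_real_, 4)
  # random baseline: per-bp category fraction under the same priority
  baseline <- local({
    bp <- stats::setNames(numeric(4), cats)
    covered <- function(df) { # bp covered by a region set (union)
      s <- 0
      for (ch in unique(df$chrom)) {
        d <- df[df$chrom == ch, ]
        ir <- IRanges::reduce(IRanges::IRanges(d$start + 1, d$end))
        s <- s + sum(IRanges::width(ir))
      }
      s
    }
    total <- sum(layout$lengths)
    tss_bp <- covered(regs$TSS_region)
    tss_tts <- covered(rbind(regs$TSS_region, regs$TTS_region))
    all3 <- covered(do.call(rbind, regs))
    bp["TSS_region"] <- tss_bp
    bp["TTS_region"] <- tss_tts - tss_bp
    bp["gene_body"] <- all3 - tss_tts
    bp["intergenic"] <- total - all3
    bp / total
  })
  list(categories = categories,
       fractions = stats::setNames(fractions, cats),
       baseline = baseline)
}

#' Gene / peak overlap labels and percentages
#'
#' A gene is positive for a peak set when any peak overlaps its span. For
#' every pair of sets the Venn-style percentages `|A&B|/|A|` and `|A&B|/|B|`
#' are reported.
#'
#' @param genes a [gene_table()].
#' @param peak_sets named list of peak data.frames.
#' @return list with `labels` (logical gene x set matrix) and `pairwise`
#'   (data.frame: set_a, set_b, pct_of_a, pct_of_b).
#' @export
gene_peak_overlap <- function(genes, peak_sets) {
  if (!length(peak_sets)) stop("need at least one peak set")
  if (is.null(names(peak_sets)))
    names(peak_sets) <- paste0("set", seq_along(peak_sets))
  labels <- sapply(peak_sets, function(p) {
    pos <- rep(FALSE, nrow(genes))
    if (nrow(p)) pos[unique(overlap_query(genes, p)$query)] <- TRUE
    pos
  })
  labels <- matrix(labels, nrow = nrow(genes),
                   dimnames = list(genes$gene_id, names(peak_sets)))
  nm <- colnames(labels)
  pw <- list()
  if (length(nm) > 1) {
    for (i in seq_along(nm)) for (j in seq_along(nm)) {
      if (i >= j) next
      a <- labels[, i]; b <- labels[, j]
      inter <- sum(a & b)
      pw[[length(pw) + 1]] <- data.frame(
        set_a = nm[i], set_b = nm[j],
        pct_of_a = if (sum(a)) 100 * inter / sum(a) else NA_real_,
        pct_of_b = if (sum(b)) 100 * inter / sum(b) else NA_real_)
    }
  }
  list(labels = labels,
       pairwise = if (length(pw)) do.call(rbind, pw) else
         data.frame(set_a = character(), set_b = character(),
                    pct_of_a = numeric(), pct_of_b = numeric()))
}

#' Widths of broad enriched domains
#'
#' Maximal runs of bins above a threshold, merged across gaps of at most
#' `merge_gap` bins — used to measure the megabase-scale spreading of
#' gamma-H2AX around break sites versus the much narrower stall (p-RPA)
#' signal.
#'
#' @param track a normalized [signal_track()].
#' @param threshold enrichment threshold on bin values.
#' @param merge_gap gap tolerance in bins.
#' @param smooth_bins centered moving-average window applied before
#'   thresholding; broad domains over a Poisson background need smoothing
#'   (window well below the expected domain width) or bin-level noise
#'   dominates the width distribution.
#' @return data.frame `chrom`, `start`, `end`, `width` (bp).
#' @export
broad_domain_width <- function(track, threshold, merge_gap = 1L,
                               smooth_bins = 1L) {
  res <- lapply(track$layout$chroms, function(ch) {
    above <- which(moving_average(track$values[[ch]], smooth_bins) >
                     threshold)
    if (!length(above)) return(NULL)
    brk <- which(diff(above) > merge_gap + 1L)
    starts <- above[c(1, brk + 1)]; ends <- above[c(brk, length(above))]
    b <- track$bin_size
    data.frame(chrom = ch, start = (starts - 1) * b,
               end = pmin(ends * b, chrom_length(track$layout, ch)))
  })
  res <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(res))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), width = numeric()))
  res$width <- res$end - res$start
  rownames(res) <- NULL
  res
}

#' Write peaks as BED6+ (name, enrichment, q-value in extra columns)
#' @param peaks peak data.frame.
#' @param path output file.
#' @export
write_peaks_bed <- function(peaks, path) {
  df <- data.frame(peaks$chrom, format_num(peaks$start),
                   format_num(peaks$end),
                   paste0("peak_", seq_len(nrow(peaks))),
                   format_num(signif(peaks$enrichment, 6)), ".",
                   format_num(peaks$summit),
                   format_num(signif(peaks$q_value, 6)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
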