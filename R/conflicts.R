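#' Analysis parameters for conflict statistics
#'
#' Houses the study's constants: converging pairs are split at a 5 kb gap,
#' anchor windows are +/- 2 kb, metagene flanks +/- 10 kb, the break-positive
#' ranking takes the top 25%, and expression is stratified into 5 quintiles.
#'
#' @param converging_gap_bp gap threshold separating close from distant
#'   converging pairs (bp).
#' @param tts_half_width anchor window half width (bp).
#' @param flank metagene flank (bp).
#' @param top_fraction fraction labeled positive by [rank_tts_dsb()].
#' @param n_boot bootstrap resamples for stratified confidence intervals.
#' @return list of class `analysis_params`.
#' @export
analysis_params <- function(converging_gap_bp = 5000, tts_half_width = 2000,
                            flank = 10000, top_fraction = 0.25,
                            n_boot = 1000) {
  stopifnot(converging_gap_bp > 0, tts_half_width > 0, flank > 0,
            top_fraction > 0, top_fraction <= 1)
  structure(list(converging_gap_bp = converging_gap_bp,
                 tts_half_width = tts_half_width, flank = flank,
                 top_fraction = top_fraction, n_boot = as.integer(n_boot),
                 n_quintiles = 5L),
            class = "analysis_params")
}

#' Classify adjacent gene pairs by relative orientation
#'
#' Every pair of neighboring genes on a chromosome is classified as
#' `converging` (upstream gene on `+`, downstream on `-`: 3' ends face each
#' other), `divergent` (the reverse) or `codirectional` (same strand). The
#' gap is `downstream.start - upstream.end`, floored at 0 for overlapping
#' pairs; for converging pairs this is the distance between the facing TTS
#' ends.
#'
#' @param genes a [gene_table()] (sorted by coordinate, as the constructor
#'   guarantees).
#' @return data.frame: `gene_a`, `gene_b` (coordinate order), `chrom`,
#'   `relation`, `gap`.
#' @export
classify_gene_pairs <- function(genes) {
  res <- list()
  for (ch in unique(genes$chrom)) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    g <- g[order(g$start, g$end, g$gene_id), , drop = FALSE]
    if (nrow(g) < 2) next
    i <- seq_len(nrow(g) - 1L)
    sa <- g$strand[i]; sb <- g$strand[i + 1L]
    relation <- ifelse(sa == sb, "codirectional",
                ifelse(sa == "+", "converging", "divergent"))
    res[[ch]] <- data.frame(gene_a = g$gene_id[i], gene_b = g$gene_id[i + 1L],
                            chrom = ch, relation = relation,
                            gap = pmax(g$start[i + 1L] - g$end[i], 0))
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(gene_a = character(), gene_b = character(),
               chrom = character(), relation = character(), gap = numeric())
  rownames(out) <- NULL
  out
}

boot_ci <- function(x, n_boot, seed) {
  if (length(x) < 2)
    return(c(lo = mean(x), hi = mean(x)))
  set.seed(seed)
  means <- vapply(seq_len(n_boot), function(i)
    mean(x[sample.int(length(x), replace = TRUE)]), numeric(1))
  stats::quantile(means, c(0.025, 0.975), names = FALSE)
}

#' TTS signal of converging pairs, stratified by gap
#'
#' Converging pairs are split at `converging_gap_bp` (< 5 kb versus >= 5 kb
#' by default); the TTS-window signal of every member gene is summarized per
#' stratum with a seeded 95% bootstrap CI, and a gap-binned curve is
#' returned alongside.
#'
#' @param pairs output of [classify_gene_pairs()].
#' @param genes a [gene_table()] covering the pair members.
#' @param track a [signal_track()].
#' @param params an [analysis_params()].
#' @param seed integer seed for the bootstrap.
#' @param gap_breaks breakpoints (bp) for the gap-binned curve.
#' @return list: `strata` (data.frame: stratum, n_genes, mean, ci_lo,
#'   ci_hi; a missing stratum is reported with n_genes = 0 and NA summaries)
#'   and `curve` (gap bin, n, mean).
#' @export
signal_by_gap <- function(pairs, genes, track, params = analysis_params(),
                          seed = 1L,
                          gap_breaks = c(0, 2000, 5000, 10000, 20000, Inf)) {
  conv <- pairs[pairs$relation == "converging", , drop = FALSE]
  tts <- anchor_of(genes, "TTS")
  score <- stats::setNames(
    window_quantify(track, tts, params$tts_half_width), genes$gene_id)
  member_scores <- function(p) as.numeric(score[c(p$gene_a, p$gene_b)])
  strata <- lapply(list(close = conv[conv$gap < params$converging_gap_bp, ],
                        far = conv[conv$gap >= params$converging_gap_bp, ]),
                   member_scores)
  summ <- do.call(rbind, lapply(names(strata), function(nm) {
    x <- strata[[nm]]; x <- x[!is.na(x)]
    if (!length(x))
      return(data.frame(stratum = nm, n_genes = 0L, mean = NA_real_,
                        ci_lo = NA_real_, ci_hi = NA_real_))
    ci <- boot_ci(x, params$n_boot, seed + match(nm, names(strata)))
    data.frame(stratum = nm, n_genes = length(x), mean = mean(x),
               ci_lo = ci[1], ci_hi = ci[2])
  }))
  gap_bin <- cut(conv$gap, gap_breaks, include.lowest = TRUE, right = FALSE)
  curve <- do.call(rbind, lapply(levels(gap_bin), function(lv) {
    x <- member_scores(conv[which(gap_bin == lv), , drop = FALSE])
    x <- x[!is.na(x)]
    data.frame(gap_bin = lv, n = length(x),
               mean = if (length(x)) mean(x) else NA_real_)
  }))
  rownames(summ) <- rownames(curve) <- NULL
  list(strata = summ, curve = curve)
}

#' Anchor-window signal by expression quintile
#'
#' @param genes a [gene_table()].
#' @param track a [signal_track()].
#' @param quintiles an [expression_quintiles()] result covering `genes`.
#' @param params an [analysis_params()].
#' @param anchor `"TTS"` (default) or `"TSS"`.
#' @return data.frame: quintile, n, mean, sem (NA rows flag empty quintiles).
#' @export
signal_by_expression <- function(genes, track, quintiles,
                                 params = analysis_params(),
                                 anchor = "TTS") {
  q <- unname(quintiles$assignment[genes$gene_id])
  score <- window_quantify(track, anchor_of(genes, anchor),
                           params$tts_half_width)
  do.call(rbind, lapply(1:5, function(k) {
    x <- score[which(q == k)]
    x <- x[!is.na(x)]
    data.frame(quintile = k, n = length(x),
               mean = if (length(x)) mean(x) else NA_real_,
               sem = if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else
                 if (length(x) == 1) 0 else NA_real_)
  }))
}

#' Signal at TSS/TTS stratified by replication orientation
#'
#' The six-cell table of mean anchor-window signal for {TSS, TTS} x
#' {HO, CD, ambiguous}, with group sizes and SEM — the genome-wide pattern
#' that stalled-fork signal concentrates at head-on-replicated TTS.
#'
#' @param genes a [gene_table()].
#' @param rfd an RFD track from [compute_rfd()].
#' @param track a [signal_track()].
#' @param params an [analysis_params()].
#' @param conflict a [conflict_params()] for the orientation calls.
#' @return data.frame: anchor, orientation, n, mean, sem.
#' @export
ho_cd_enrichment <- function(genes, rfd, track, params = analysis_params(),
                             conflict = conflict_params()) {
  do.call(rbind, lapply(c("TSS", "TTS"), function(kind) {
    ori <- orientation_at(genes, kind, rfd, conflict)
    score <- window_quantify(track, anchor_of(genes, kind),
                             params$tts_half_width)
    do.call(rbind, lapply(c("HO", "CD", "ambiguous"), function(o) {
      x <- score[ori$orientation == o]
      x <- x[!is.na(x)]
      data.frame(anchor = kind, orientation = o, n = length(x),
                 mean = if (length(x)) mean(x) else NA_real_,
                 sem = if (length(x) > 1) stats::sd(x) / sqrt(length(x))
                       else if (length(x) == 1) 0 else NA_real_)
    }))
  }))
}

#' TTS signal versus distance to the downstream replication origin
#'
#' @param genes a [gene_table()].
#' @param zones initiation zones from [detect_initiation_zones()].
#' @param track a [signal_track()].
#' @param params an [analysis_params()].
#' @param breaks distance bin breakpoints in bp (monotone).
#' @return list: `curve` (data.frame distance bin, midpoint, n, mean, sem),
#'   `excluded` (genes with no downstream zone), `spearman` (correlation of
#'   per-gene distance and signal).
#' @export
signal_vs_origin_distance <- function(genes, zones, track,
                                      params = analysis_params(),
                                      breaks = c(0, 1e4, 2.5e4, 5e4, 1e5,
                                                 2e5)) {
  d <- distance_to_downstream_origin(genes, zones)
  score <- window_quantify(track, anchor_of(genes, "TTS"),
                           params$tts_half_width)
  keep <- !is.na(d) & !is.na(score)
  excluded <- sum(!keep)
  d <- d[keep]; score <- score[keep]
  bin <- cut(d, breaks, include.lowest = TRUE, right = FALSE)
  mids <- (breaks[-length(breaks)] + breaks[-1]) / 2
  curve <- do.call(rbind, lapply(seq_along(levels(bin)), function(k) {
    x <- score[which(as.integer(bin) == k)]
    data.frame(bin = levels(bin)[k], midpoint = mids[k], n = length(x),
               mean = if (length(x)) mean(x) else NA_real_,
               sem = if (length(x) > 1) stats::sd(x) / sqrt(length(x))
                     else if (length(x) == 1) 0 else NA_real_)
  }))
  sp <- if (length(d) > 2)
    suppressWarnings(stats::cor(d, score, method = "spearman")) else NA_real_
  list(curve = curve, excluded = excluded, spearman = sp)
}
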