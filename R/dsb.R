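#' Rank genes by break signal at the TTS and label the top fraction
#'
#' Scores each gene by the mean i-BLESS signal in a +/- 2 kb window on the
#' TTS after reads-per-million scaling, sorts descending (ties broken by
#' gene id), and labels the top `ceiling(fraction * N)` genes positive.
#'
#' @param track a raw i-BLESS [signal_track()].
#' @param genes a [gene_table()].
#' @param params an [analysis_params()] (`top_fraction`, `tts_half_width`).
#' @param anchor `"TTS"` (default) or `"TSS"` for the promoter-break variant.
#' @return list: `scores` (data.frame gene_id, score, rank, top — sorted by
#'   rank), `top_ids`, `degenerate` (TRUE when every score is identical and
#'   the label set is tie-break order only).
#' @export
rank_tts_dsb <- function(track, genes, params = analysis_params(),
                         anchor = "TTS") {
  scaled <- scale_track(track)
  score <- window_quantify(scaled, anchor_of(genes, anchor),
                           params$tts_half_width)
  ord <- order(-score, genes$gene_id)
  n_top <- ceiling(params$top_fraction * nrow(genes))
  df <- data.frame(gene_id = genes$gene_id[ord], score = score[ord],
                   rank = seq_along(ord),
                   top = seq_along(ord) <= n_top)
  list(scores = df, top_ids = df$gene_id[df$top],
       degenerate = length(unique(df$score)) == 1L)
}

#' Classify DSB+ / DSB- genes by hierarchical clustering
#'
#' Agglomerative clustering (Ward linkage, Euclidean distance) on the
#' standardized per-gene feature matrix — by default the (control, shTop1)
#' TTS break scores — cut at k = 2; the cluster with the higher mean shTop1
#' score is labeled DSB+.
#'
#' @param features numeric matrix (genes x features) with rownames = gene
#'   ids; conventionally columns `control` and `shTop1`.
#' @param positive_by column whose cluster mean decides the DSB+ label
#'   (default the last column, i.e. shTop1).
#' @param linkage linkage method for [stats::hclust()] (default `ward.D2`).
#' @return list of class `dsb_classification`: `labels` (named character,
#'   "DSB+"/"DSB-"), `features`, `degenerate` (all-identical rows: one
#'   cluster, everything DSB- with a warning).
#' @export
cluster_dsb_genes <- function(features, positive_by = ncol(features),
                              linkage = "ward.D2") {
  if (is.null(rownames(features))) stop("features must have gene-id rownames")
  if (nrow(features) < 2) stop("need at least 2 genes")
  if (any(!is.finite(features))) stop("features must be finite")
  if (all(apply(features, 2, function(x) length(unique(x)) == 1L))) {
    warning("all feature rows identical: degenerate single cluster, all DSB-")
    return(structure(list(
      labels = stats::setNames(rep("DSB-", nrow(features)),
                               rownames(features)),
      features = features, degenerate = TRUE),
      class = "dsb_classification"))
  }
  std <- scale(features)
  std[, apply(features, 2, function(x) length(unique(x)) == 1L)] <- 0
  cl <- stats::cutree(stats::hclust(stats::dist(std), method = linkage),
                      k = 2)
  m1 <- mean(features[cl == 1, positive_by])
  m2 <- mean(features[cl == 2, positive_by])
  pos <- if (m1 >= m2) 1L else 2L
  structure(list(
    labels = stats::setNames(ifelse(cl == pos, "DSB+", "DSB-"),
                             rownames(features)),
    features = features, degenerate = FALSE),
    class = "dsb_classification")
}

#' Wilcoxon rank-sum test with continuity correction
#'
#' Two-sided Mann-Whitney rank-sum test using the normal approximation with
#' tie correction and continuity correction — the comparison used for all
#' group contrasts of anchor-window signal.
#'
#' @param a,b numeric vectors (each non-empty; ties allowed).
#' @return list: `statistic` (Mann-Whitney U of `a`), `p_value` in (0, 1].
#' @export
compare_groups <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  ties <- table(r)
  sigma2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(statistic = U, p_value = 1))
  cc <- sign(U - mu) * 0.5
  z <- (U - mu - cc) / sqrt(sigma2)
  p <- min(2 * stats::pnorm(-abs(z)), 1)
  list(statistic = U, p_value = max(p, .Machine$double.xmin))
}

#' Orientation composition of DSB+ versus DSB- genes
#'
#' For each group, the percentage of member genes whose TTS faces a
#' converging (head-on, HO) or codirectional (CD) neighbor, with a two-
#' proportion z-test on the HO fraction.
#'
#' @param classification a [cluster_dsb_genes()] result (or any list with a
#'   `labels` element).
#' @param orientation named character vector (gene id -> "HO"/"CD"), e.g.
#'   from [orientation_at()] on the TTS, or from pair geometry.
#' @return list: `table` (data.frame group, n, pct_HO, pct_CD), `p_value`
#'   of the two-proportion z-test (NA when a group is empty).
#' @export
orientation_composition <- function(classification, orientation) {
  lab <- classification$labels
  common <- intersect(names(lab), names(orientation))
  lab <- lab[common]; ori <- orientation[common]
  keep <- ori %in% c("HO", "CD")
  lab <- lab[keep]; ori <- ori[keep]
  tab <- do.call(rbind, lapply(c("DSB+", "DSB-"), function(g) {
    o <- ori[lab == g]
    data.frame(group = g, n = length(o),
               pct_HO = if (length(o)) 100 * mean(o == "HO") else NA_real_,
               pct_CD = if (length(o)) 100 * mean(o == "CD") else NA_real_)
  }))
  p <- NA_real_
  if (all(tab$n > 0)) {
    x <- c(sum(ori[lab == "DSB+"] == "HO"), sum(ori[lab == "DSB-"] == "HO"))
    n <- tab$n
    ph <- sum(x) / sum(n)
    se <- sqrt(ph * (1 - ph) * (1 / n[1] + 1 / n[2]))
    p <- if (se > 0) 2 * stats::pnorm(-abs((x[1] / n[1] - x[2] / n[2]) / se))
         else 1
  }
  list(table = tab, p_value = p)
}

#' Group metaprofiles and rank-sum contrasts for a DSB classification
#'
#' For every track, builds the DSB+ and DSB- anchor metaprofiles and tests
#' the difference in TTS-window signal between the groups with
#' [compare_groups()].
#'
#' @param classification a [cluster_dsb_genes()]-style result.
#' @param tracks named list of [signal_track()]s (DRIP, p-RPA, ...).
#' @param genes a [gene_table()] covering the classified genes.
#' @param params an [analysis_params()].
#' @return list per track: `profile_pos`, `profile_neg` ([meta_profile()]s),
#'   `mean_pos`, `mean_neg`, `p_value`.
#' @export
group_signal_profiles <- function(classification, tracks, genes,
                                  params = analysis_params()) {
  lab <- classification$labels
  genes <- genes[genes$gene_id %in% names(lab), , drop = FALSE]
  pos <- genes[lab[genes$gene_id] == "DSB+", , drop = FALSE]
  neg <- genes[lab[genes$gene_id] == "DSB-", , drop = FALSE]
  lapply(tracks, function(tr) {
    sp <- window_quantify(tr, anchor_of(pos, "TTS"), params$tts_half_width)
    sn <- window_quantify(tr, anchor_of(neg, "TTS"), params$tts_half_width)
    list(profile_pos = meta_profile(tr, pos, mode = "anchor", anchor = "TTS",
                                    flank = params$flank),
         profile_neg = meta_profile(tr, neg, mode = "anchor", anchor = "TTS",
                                    flank = params$flank),
         mean_pos = mean(sp, na.rm = TRUE), mean_neg = mean(sn, na.rm = TRUE),
         p_value = compare_groups(sp, sn)$p_value)
  })
}
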