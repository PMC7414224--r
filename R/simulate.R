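#' Configuration of the synthetic multi-omics genome
#'
#' One seeded configuration drives the whole generator: a single toy
#' chromosome packed with non-overlapping genes whose strands follow a
#' Markov switch process (so roughly 30% of adjacent pairs converge),
#' log-normal expression with a zero-expression fraction, replication
#' origins enriched at promoters of highly expressed genes, and
#' condition-specific signal tracks. All stochastic draws derive from
#' `seed`.
#'
#' @param seed integer master seed.
#' @param chrom_length chromosome length L in bp (divisible by `bin_size`).
#' @param bin_size track/OK-seq bin width in bp.
#' @param n_genes number of genes to pack.
#' @param zero_expr_fraction fraction of silent (RPKM = 0) genes.
#' @param expr_meanlog,expr_sdlog log-normal RPKM parameters for expressed
#'   genes.
#' @param len_meanlog,len_sdlog,len_min,len_max gene-length model (log-normal,
#'   clamped).
#' @param gap_close,gap_far uniform ranges (bp) of the two-component
#'   intergenic gap mixture; `p_gap_close` is the weight of the short
#'   component, so about half of converging gaps fall below 5 kb.
#' @param strand_switch probability that a gene's strand differs from its
#'   left neighbor (0.6 gives ~30% converging adjacent pairs).
#' @param promoter_origin_prob named probabilities of a promoter-proximal
#'   origin for `top` quintile, `other` active, and `silent` genes.
#' @param intergenic_origin_rate Poisson rate of background origins per bp.
#' @param efficiency_range uniform range of origin firing efficiencies.
#' @param origin_min_spacing minimum spacing enforced between origins (bp);
#'   candidates are thinned keeping the most efficient first.
#' @param promoter_offset uniform range (bp) of origin placement upstream of
#'   the TSS.
#' @param n_cells Monte-Carlo cells for the true RFD field.
#' @param okseq_depth mean Okazaki fragments per bin.
#' @param bump_sigma Gaussian sd (bp) of planted DRIP / p-RPA bumps.
#' @param drip_bg,drip_amp,prpa_bg,prpa_amp,gh2ax_bg,gh2ax_amp,ibless_bg,ibless_amp
#'   per-track Poisson background means and planted amplitudes (counts/bin;
#'   bump amplitudes scale with `log1p(RPKM)`).
#' @param drip_converging_boost multiplier on the DRIP TTS bump of converging
#'   genes separated by < 5 kb (1 disables the effect).
#' @param dsb_fraction fraction of active genes planted DSB+ (shTop1).
#' @param dsb_orientation_bias prefer high-expression head-on TTS when
#'   drawing DSB+ genes (FALSE plants them uniformly).
#' @param dsb_leak fraction of the DSB+ set drawn uniformly regardless of
#'   bias, keeping recovery tests non-trivial.
#' @param gh2ax_width flat-top gamma-H2AX domain width (bp) around DSB+ TTS.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       chrom_length = 2e7, bin_size = 1000, n_genes = 2000,
                       zero_expr_fraction = 0.2,
                       expr_meanlog = 1, expr_sdlog = 1.5,
                       len_meanlog = log(3500), len_sdlog = 0.5,
                       len_min = 1000, len_max = 15000,
                       gap_close = c(300, 4800), gap_far = c(5200, 10000),
                       p_gap_close = 0.5, strand_switch = 0.6,
                       promoter_origin_prob = c(top = 0.7, other = 0.25,
                                                silent = 0.05),
                       intergenic_origin_rate = 1 / 2e5,
                       efficiency_range = c(0.2, 0.9),
                       origin_min_spacing = 20000,
                       promoter_offset = c(500, 2500),
                       n_cells = 200, okseq_depth = 500,
                       bump_sigma = 1500,
                       drip_bg = 5, drip_amp = 12,
                       prpa_bg = 5, prpa_amp = 12,
                       gh2ax_bg = 2, gh2ax_amp = 8,
                       ibless_bg = 2, ibless_amp = 20,
                       drip_converging_boost = 2,
                       dsb_fraction = 0.27, dsb_orientation_bias = TRUE,
                       dsb_leak = 0.1, gh2ax_width = 1e5) {
  cfg <- as.list(environment())
  if (cfg$chrom_length %% cfg$bin_size != 0)
    stop("chrom_length must be divisible by bin_size")
  rates <- c(zero_expr_fraction, p_gap_close, strand_switch,
             promoter_origin_prob, dsb_fraction, dsb_leak)
  if (any(rates < 0 | rates > 1)) stop("all rates must be in [0, 1]")
  structure(cfg, class = "sim_config")
}

#' Simulate the toy genome: genes, origins, and the true RFD field
#'
#' Genes are packed left to right with mixture-distributed gaps and
#' Markov-switching strands. Replication origins are placed upstream of
#' promoters with expression-dependent probability plus a Poisson scatter of
#' intergenic origins, thinned to a minimum spacing (most efficient kept).
#' The true RFD field is a Monte-Carlo average over `n_cells` cells: each
#' origin fires independently with its efficiency, every bin is replicated
#' by the nearest firing origin, and the fork direction at a bin is the sign
#' of (bin center - origin).
#'
#' @param config a [sim_config()].
#' @return list: `layout`, `genes` (a [gene_table()]), and `truth` — the
#'   planted ground truth (origins, `rfd_true` per bin, orientation labels
#'   at TSS/TTS from the true field, DSB+ gene ids, planted bump tables,
#'   and the config).
#' @export
simulate_genome <- function(config = sim_config()) {
  cfg <- config
  set.seed(cfg$seed)
  chrom <- "chrS"
  layout <- genome_layout(chrom, cfg$chrom_length)
  N <- cfg$n_genes

  # strands: Markov switch process
  strand <- character(N)
  strand[1] <- sample(c("+", "-"), 1)
  flips <- stats::runif(N - 1) < cfg$strand_switch
  for (i in 2:N)
    strand[i] <- if (flips[i - 1]) setdiff(c("+", "-"), strand[i - 1]) else
      strand[i - 1]

  len <- pmin(pmax(round(stats::rlnorm(N, cfg$len_meanlog, cfg$len_sdlog)),
                   cfg$len_min), cfg$len_max)
  close <- stats::runif(N) < cfg$p_gap_close
  gap <- ifelse(close,
                stats::runif(N, cfg$gap_close[1], cfg$gap_close[2]),
                stats::runif(N, cfg$gap_far[1], cfg$gap_far[2]))
  gap <- round(gap)
  start <- cumsum(gap) + cumsum(c(0, len[-N]))
  end <- start + len
  if (end[N] > cfg$chrom_length)
    stop("infeasible packing: ", N, " genes need ", end[N],
         " bp but chromosome is ", cfg$chrom_length, " bp")

  expr <- ifelse(stats::runif(N) < cfg$zero_expr_fraction, 0,
                 stats::rlnorm(N, cfg$expr_meanlog, cfg$expr_sdlog))
  genes <- gene_table(sprintf("g%04d", seq_len(N)), chrom, start, end,
                      strand, expr, layout = layout)

  # promoter origins, probability by expression class
  qa <- expression_quintiles(genes)$assignment[genes$gene_id]
  cls <- ifelse(genes$expression_rpkm == 0, "silent",
                ifelse(qa == 1, "top", "other"))
  p_orig <- cfg$promoter_origin_prob[cls]
  has_orig <- stats::runif(N) < p_orig
  offs <- round(stats::runif(N, cfg$promoter_offset[1],
                             cfg$promoter_offset[2]))
  tss <- anchor_of(genes, "TSS")$position
  prom_pos <- ifelse(genes$strand == "+", tss - offs, tss + offs)
  prom_pos <- pmin(pmax(prom_pos[has_orig], 0), cfg$chrom_length - 1)
  n_inter <- stats::rpois(1, cfg$intergenic_origin_rate * cfg$chrom_length)
  inter_pos <- round(stats::runif(n_inter, 0, cfg$chrom_length - 1))
  pos <- c(prom_pos, inter_pos)
  eff <- stats::runif(length(pos), cfg$efficiency_range[1],
                      cfg$efficiency_range[2])
  # thin to min spacing, most efficient first
  ord <- order(-eff, pos)
  keep_pos <- numeric(0); keep <- logical(length(pos))
  for (i in ord) {
    if (!length(keep_pos) || min(abs(keep_pos - pos[i])) >=
        cfg$origin_min_spacing) {
      keep[i] <- TRUE; keep_pos <- c(keep_pos, pos[i])
    }
  }
  origins <- data.frame(position = pos[keep], efficiency = eff[keep])
  origins <- origins[order(origins$position), , drop = FALSE]
  rownames(origins) <- NULL

  rfd_true <- rfd_field(origins, cfg)
  b <- cfg$bin_size
  sgn <- ifelse(genes$strand == "+", 1, -1)
  tts <- anchor_of(genes, "TTS")$position
  s_tts <- sgn * rfd_true[floor(tts / b) + 1]
  s_tss <- sgn * rfd_true[floor(anchor_of(genes, "TSS")$position / b) + 1]
  ori_lab <- function(s) ifelse(s < 0, "HO", ifelse(s > 0, "CD", "none"))

  active <- genes$gene_id[genes$expression_rpkm > 0]
  n_dsb <- round(cfg$dsb_fraction * length(active))
  amp_e <- log1p(genes$expression_rpkm)
  names(amp_e) <- genes$gene_id
  w <- if (cfg$dsb_orientation_bias)
    amp_e[active] * ifelse(ori_lab(s_tts)[match(active, genes$gene_id)] ==
                             "HO", 3, 0.3)
  else rep(1, length(active))
  n_leak <- round(cfg$dsb_leak * n_dsb)
  dsb <- sample(active, n_dsb - n_leak, prob = w)
  rest <- setdiff(active, dsb)
  if (n_leak > 0 && length(rest))
    dsb <- c(dsb, sample(rest, min(n_leak, length(rest))))

  pairs <- classify_gene_pairs(genes)
  conv_close <- pairs[pairs$relation == "converging" & pairs$gap < 5000, ]
  boosted <- unique(c(conv_close$gene_a, conv_close$gene_b))

  bump_tab <- function(ids, anchor, amp) {
    a <- anchor_of(genes[match(ids, genes$gene_id), , drop = FALSE], anchor)
    data.frame(gene_id = ids, anchor = anchor, chrom = a$chrom,
               center = a$position, amplitude = amp)
  }
  drip_tss <- bump_tab(active, "TSS", cfg$drip_amp * amp_e[active])
  drip_tts <- bump_tab(active, "TTS", cfg$drip_amp * amp_e[active] *
                         ifelse(active %in% boosted,
                                cfg$drip_converging_boost, 1))
  prpa_amp <- cfg$prpa_amp * amp_e[active] *
    pmax(0, -s_tts[match(active, genes$gene_id)])
  prpa_tts <- bump_tab(active, "TTS", prpa_amp)

  truth <- list(layout = layout, genes = genes, config = cfg,
                origins = origins,
                rfd_true = stats::setNames(list(rfd_true), chrom),
                orientation_tss = stats::setNames(ori_lab(s_tss),
                                                  genes$gene_id),
                orientation_tts = stats::setNames(ori_lab(s_tts),
                                                  genes$gene_id),
                signed_rfd_tts = stats::setNames(s_tts, genes$gene_id),
                active = active, dsb_positive = sort(dsb),
                converging_boosted = boosted,
                planted_drip = rbind(drip_tss, drip_tts),
                planted_prpa = prpa_tts[prpa_tts$amplitude > 0, ,
                                        drop = FALSE])
  list(layout = layout, genes = genes, truth = truth)
}

# Monte-Carlo true RFD: nearest firing origin replicates each bin
rfd_field <- function(origins, cfg) {
  nb <- cfg$chrom_length %/% cfg$bin_size
  centers <- (seq_len(nb) - 0.5) * cfg$bin_size
  acc <- numeric(nb)
  pos <- origins$position; eff <- origins$efficiency
  for (cell in seq_len(cfg$n_cells)) {
    fired <- pos[stats::runif(length(pos)) < eff]
    if (!length(fired)) next
    fired <- sort(fired)
    k <- findInterval(centers, fired)
    left <- fired[pmax(k, 1)]
    right <- fired[pmin(k + 1, length(fired))]
    dl <- ifelse(k >= 1, centers - left, Inf)
    dr <- ifelse(k < length(fired), right - centers, Inf)
    acc <- acc + ifelse(dl <= dr, 1, -1)
  }
  acc / cfg$n_cells
}

#' Simulate stranded Okazaki-fragment counts from the true RFD field
#'
#' Per bin the total fragment count is Poisson(`depth`) and the Crick count
#' is Binomial(total, (1 + RFD_true) / 2); Watson is the remainder. A bin
#' with RFD_true = +1 therefore never yields Watson fragments.
#'
#' @param truth the `truth` element of [simulate_genome()].
#' @param depth mean fragments per bin (0 gives all-zero counts).
#' @return a [stranded_bin_counts()].
#' @export
simulate_okseq <- function(truth, depth = truth$config$okseq_depth) {
  if (depth < 0) stop("depth must be >= 0")
  cfg <- truth$config
  set.seed(cfg$seed + 101L)
  W <- list(); C <- list()
  for (ch in truth$layout$chroms) {
    r <- truth$rfd_true[[ch]]
    tot <- if (depth > 0) stats::rpois(length(r), depth) else
      integer(length(r))
    crick <- stats::rbinom(length(r), tot, (1 + r) / 2)
    C[[ch]] <- crick
    W[[ch]] <- tot - crick
  }
  stranded_bin_counts(truth$layout, cfg$bin_size, W, C)
}

#' Simulate the condition-specific signal tracks
#'
#' Raw Poisson counts per bin around planted structure: DRIP IP carries
#' Gaussian bumps at the TSS and TTS of active genes (amplitude scaling with
#' log1p(RPKM), boosted at close converging TTS) over background; DRIP input
#' is background only; p-RPA carries a TTS bump gated by the true head-on
#' fork fraction; i-BLESS and gamma-H2AX carry signal only in the shTop1
#' condition, confined to DSB+ genes (sharp TTS +/- 2 kb windows and broad
#' flat-top domains respectively).
#'
#' @param truth the `truth` element of [simulate_genome()].
#' @param condition `"control"` or `"shTop1"`.
#' @return named list of raw [signal_track()]s: `drip_ip`, `drip_input`,
#'   `prpa`, `gh2ax`, `ibless`.
#' @export
simulate_tracks <- function(truth, condition = c("control", "shTop1")) {
  condition <- match.arg(condition)
  cfg <- truth$config
  set.seed(cfg$seed + 211L + if (condition == "shTop1") 1000L else 0L)
  ch <- truth$layout$chroms[1]
  nb <- cfg$chrom_length %/% cfg$bin_size
  b <- cfg$bin_size
  centers <- (seq_len(nb) - 0.5) * b

  add_bumps <- function(intensity, tab) {
    span <- ceiling(5 * cfg$bump_sigma / b)
    for (i in seq_len(nrow(tab))) {
      cb <- floor(tab$center[i] / b) + 1
      idx <- max(1, cb - span):min(nb, cb + span)
      d <- centers[idx] - tab$center[i]
      intensity[idx] <- intensity[idx] +
        tab$amplitude[i] * exp(-d^2 / (2 * cfg$bump_sigma^2))
    }
    intensity
  }
  add_window <- function(intensity, positions, half, amp) {
    for (p in positions) {
      idx <- max(1, floor((p - half) / b) + 1):min(nb, ceiling((p + half) / b))
      intensity[idx] <- intensity[idx] + amp
    }
    intensity
  }
  draw <- function(intensity)
    signal_track(truth$layout, b,
                 stats::setNames(list(stats::rpois(nb, intensity)), ch),
                 flavor = "raw")

  drip_int <- add_bumps(rep(cfg$drip_bg, nb), truth$planted_drip)
  prpa_int <- add_bumps(rep(cfg$prpa_bg, nb), truth$planted_prpa)
  gh2ax_int <- rep(cfg$gh2ax_bg, nb)
  ibless_int <- rep(cfg$ibless_bg, nb)
  if (condition == "shTop1" && length(truth$dsb_positive)) {
    dsb_genes <- truth$genes[match(truth$dsb_positive,
                                   truth$genes$gene_id), , drop = FALSE]
    tts <- anchor_of(dsb_genes, "TTS")$position
    gh2ax_int <- add_window(gh2ax_int, tts, cfg$gh2ax_width / 2,
                            cfg$gh2ax_amp)
    ibless_int <- add_window(ibless_int, tts, 2000, cfg$ibless_amp)
  }
  list(drip_ip = draw(drip_int), drip_input = draw(rep(cfg$drip_bg, nb)),
       prpa = draw(prpa_int), gh2ax = draw(gh2ax_int),
       ibless = draw(ibless_int))
}

#' Run the full generator: genome, OK-seq counts, and both conditions
#'
#' @param config a [sim_config()].
#' @return list: `layout`, `genes`, `truth`, `okseq`, and `tracks`
#'   (`$control`, `$shTop1`, each a [simulate_tracks()] result).
#' @export
simulate_experiment <- function(config = sim_config()) {
  g <- simulate_genome(config)
  list(layout = g$layout, genes = g$genes, truth = g$truth,
       okseq = simulate_okseq(g$truth),
       tracks = list(control = simulate_tracks(g$truth, "control"),
                     shTop1 = simulate_tracks(g$truth, "shTop1")))
}

#' Write a simulated experiment to disk
#'
#' Emits `chrom.sizes`, `genes.bed`, `okseq.tsv`, one bedGraph per track per
#' condition, and `truth.json` (origins, DSB+ ids, orientation labels) under
#' `dir`.
#'
#' @param sim a [simulate_experiment()] result.
#' @param dir output directory (created if absent).
#' @return invisibly, the vector of files written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(
    write_chrom_sizes(sim$layout, file.path(dir, "chrom.sizes")),
    write_gene_annotation(sim$genes, file.path(dir, "genes.bed")),
    write_okseq(sim$okseq, file.path(dir, "okseq.tsv")))
  for (cond in names(sim$tracks))
    for (tr in names(sim$tracks[[cond]]))
      files <- c(files, write_bedgraph(
        sim$tracks[[cond]][[tr]],
        file.path(dir, paste0(tr, ".", cond, ".bedGraph"))))
  truth <- sim$truth
  jsonlite::write_json(
    list(origins = truth$origins, active = truth$active,
         dsb_positive = truth$dsb_positive,
         orientation_tts = as.list(truth$orientation_tts),
         converging_boosted = truth$converging_boosted,
         seed = truth$config$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(c(files, file.path(dir, "truth.json")))
}
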