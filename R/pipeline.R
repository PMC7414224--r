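#' Read a pipeline configuration
#'
#' The configuration is a JSON document (chosen as the one structured-text
#' dialect; see the methods vignette). Top-level keys: `mode`
#' (`"simulate"` or `"files"`), `sim` (overrides for [sim_config()]),
#' `inputs` (paths used in files mode: `chrom_sizes`, `genes`, `okseq`,
#' `expression`, `tracks` per condition), `params` (overrides for
#' [analysis_params()], [conflict_params()], [peak_call_config()]), and
#' `seed`. Every study constant (3 kb feature flanks, +/- 10 kb metagene
#' flank, +/- 2 kb TTS window, 5 kb converging gap, q = 0.05, top 25%,
#' 5 quintiles) is a named key with the study default.
#'
#' @param path JSON file, or a list already in memory.
#' @return list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (is.character(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else as.list(path)
  defaults <- list(mode = "simulate", sim = list(), inputs = list(),
                   params = list(), seed = 1L)
  cfg <- utils::modifyList(defaults, cfg)
  structure(cfg, class = "pipeline_config")
}

apply_overrides <- function(ctor, overrides) {
  ok <- intersect(names(overrides), names(formals(ctor)))
  do.call(ctor, overrides[ok])
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) format_num(signif(x, 10)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the integrated transcription-replication conflict pipeline
#'
#' Wires the stages end to end: simulate (or load) the inputs, derive RFD
#' and initiation zones from the OK-seq counts, call and annotate DRIP
#' peaks, build expression-stratified profiles and heatmaps, compute the
#' conflict statistics (gap strata, HO/CD table, origin-distance curve), and
#' classify DSB+ genes from the i-BLESS signal. All randomness derives from
#' the config seed, so two runs with the same seed produce byte-identical
#' outputs.
#'
#' @param config a [read_pipeline_config()] result, a path to one, or a
#'   plain list.
#' @param outdir output directory.
#' @param seed optional override of the config seed.
#' @param resume reuse stage results cached under `outdir/.state/` from a
#'   previous run instead of recomputing them.
#' @param log_level `"info"` or `"quiet"`.
#' @return invisibly, a list with the stage results and the manifest of
#'   written files.
#' @export
run_pipeline <- function(config, outdir, seed = NULL, resume = FALSE,
                         log_level = "info") {
  cfg <- if (inherits(config, "pipeline_config")) config else
    read_pipeline_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  state_dir <- file.path(outdir, ".state")
  dir.create(state_dir, showWarnings = FALSE)
  log_file <- file.path(outdir, "pipeline.log")
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    cat(msg, "\n", file = log_file, append = TRUE)
    if (log_level != "quiet") message(msg)
  }
  stage <- function(name, fun) {
    cache <- file.path(state_dir, paste0(name, ".rds"))
    if (resume && file.exists(cache)) {
      say("stage ", name, ": resumed from cache")
      return(readRDS(cache))
    }
    t0 <- Sys.time()
    res <- fun()
    saveRDS(res, cache)
    say("stage ", name, ": done in ",
        round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 1), " s")
    res
  }
  manifest <- character(0)
  emit <- function(path) { manifest <<- c(manifest, path); path }

  ap <- apply_overrides(analysis_params, cfg$params)
  cp <- apply_overrides(conflict_params, cfg$params)
  pc <- apply_overrides(peak_call_config, cfg$params)

  ## ---- inputs ----
  data <- stage("simulate", function() {
    if (identical(cfg$mode, "simulate")) {
      sc <- apply_overrides(sim_config, utils::modifyList(
        as.list(cfg$sim), list(seed = cfg$seed)))
      sim <- simulate_experiment(sc)
      for (f in write_simulation(sim, file.path(outdir, "sim"))) emit(f)
      sim
    } else {
      need <- function(key) {
        p <- cfg$inputs[[key]]
        if (is.null(p)) stop("config is missing required input path: ", key)
        if (!file.exists(p)) stop("input file not found (", key, "): ", p)
        p
      }
      layout <- read_chrom_sizes(need("chrom_sizes"))
      genes <- read_gene_annotation(need("genes"), layout)
      if (!is.null(cfg$inputs$expression))
        genes <- attach_expression(genes, need("expression"))
      bin <- if (!is.null(cfg$inputs$bin_size)) cfg$inputs$bin_size else 1000
      tracks <- lapply(cfg$inputs$tracks, function(cond)
        lapply(cond, function(p) read_bedgraph(p, layout, bin,
                                               flavor = "raw")))
      list(layout = layout, genes = genes, truth = NULL,
           okseq = read_okseq(need("okseq"), layout, bin), tracks = tracks)
    }
  })
  genes <- data$genes
  active <- filter_active(genes)

  ## ---- RFD and initiation zones ----
  repl <- stage("rfd", function() {
    rfd <- compute_rfd(data$okseq, cp)
    zones <- detect_initiation_zones(rfd, cp)
    rfd_out <- rfd
    rfd_out$values <- lapply(rfd$values, function(v) ifelse(is.na(v), 0, v))
    emit(write_bedgraph(rfd_out, file.path(outdir, "rfd.bedGraph")))
    emit(write_zones_bed(zones, file.path(outdir, "zones.bed")))
    list(rfd = rfd, zones = zones)
  })

  ## ---- peak calling and annotation ----
  peaks <- stage("callpeaks", function() {
    out <- list()
    for (cond in names(data$tracks)) {
      p <- call_peaks(data$tracks[[cond]]$drip_ip,
                      data$tracks[[cond]]$drip_input, pc)
      emit(write_peaks_bed(p, file.path(
        outdir, paste0("peaks_drip_", cond, ".bed"))))
      out[[cond]] <- p
    }
    ann <- annotate_peaks(out[[1]], genes, data$layout)
    emit(write_tsv(data.frame(category = names(ann$fractions),
                              fraction = unname(ann$fractions),
                              random_baseline = unname(ann$baseline)),
                   file.path(outdir, "peak_annotation.tsv")))
    ov <- gene_peak_overlap(genes, out)
    emit(write_tsv(ov$pairwise, file.path(outdir,
                                          "gene_peak_overlap.tsv")))
    list(peaks = out, annotation = ann, overlap = ov)
  })

  ## ---- profiles and heatmaps ----
  quint <- expression_quintiles(genes)
  prof <- stage("profile", function() {
    norm <- ip_over_input(data$tracks[[1]]$drip_ip,
                          data$tracks[[1]]$drip_input)
    mp <- meta_profile(norm, active, mode = "scaled", flank = ap$flank)
    emit(write_tsv(data.frame(column = seq_along(mp$mean), mean = mp$mean,
                              sem = mp$sem),
                   file.path(outdir, "metaprofile_drip.tsv")))
    hm_tracks <- list(DRIP = norm,
                      pRPA = scale_track(data$tracks[[1]]$prpa),
                      gH2AX = scale_track(data$tracks[[1]]$gh2ax))
    hm <- tts_heatmap(hm_tracks, genes, quint, half_width = ap$flank)
    for (nm in names(hm$matrices)) {
      m <- hm$matrices[[nm]]
      df <- data.frame(gene_id = rownames(m), quintile = hm$quintile)
      df <- cbind(df, as.data.frame(signif(m, 6)))
      emit(write_tsv(df, file.path(outdir,
                                   paste0("heatmap_", nm, ".tsv"))))
    }
    list(metaprofile = mp, heatmap = hm)
  })

  ## ---- conflict statistics ----
  confl <- stage("conflicts", function() {
    pairs <- classify_gene_pairs(genes)
    emit(write_tsv(pairs, file.path(outdir, "gene_pairs.tsv")))
    drip <- scale_track(data$tracks[[1]]$drip_ip)
    prpa <- scale_track(data$tracks[[1]]$prpa)
    gap <- signal_by_gap(pairs, genes, drip, ap, seed = cfg$seed)
    emit(write_tsv(gap$strata, file.path(outdir, "gap_strata.tsv")))
    sbe <- signal_by_expression(active, prpa,
                                expression_quintiles(active), ap)
    emit(write_tsv(sbe, file.path(outdir, "signal_by_quintile.tsv")))
    hc <- ho_cd_enrichment(active, repl$rfd, prpa, ap, cp)
    emit(write_tsv(hc, file.path(outdir, "ho_cd_table.tsv")))
    od <- signal_vs_origin_distance(active, repl$zones, prpa, ap)
    emit(write_tsv(od$curve, file.path(outdir, "origin_distance_curve.tsv")))
    list(pairs = pairs, gap = gap, by_expression = sbe, ho_cd = hc,
         origin_distance = od)
  })

  ## ---- DSB classification ----
  dsb <- stage("dsb", function() {
    if (!all(c("control", "shTop1") %in% names(data$tracks)))
      return(NULL)
    sco_c <- rank_tts_dsb(data$tracks$control$ibless, active, ap)
    sco_s <- rank_tts_dsb(data$tracks$shTop1$ibless, active, ap)
    feats <- cbind(control = sco_c$scores$score[
                     match(active$gene_id, sco_c$scores$gene_id)],
                   shTop1 = sco_s$scores$score[
                     match(active$gene_id, sco_s$scores$gene_id)])
    rownames(feats) <- active$gene_id
    cl <- cluster_dsb_genes(feats)
    emit(write_tsv(data.frame(gene_id = active$gene_id,
                              label = unname(cl$labels[active$gene_id]),
                              control = feats[, "control"],
                              shTop1 = feats[, "shTop1"]),
                   file.path(outdir, "dsb_classification.tsv")))
    ori <- truth_free_orientation(confl$pairs, active)
    comp <- orientation_composition(cl, ori)
    grp <- group_signal_profiles(cl, list(
      DRIP = scale_track(data$tracks$shTop1$drip_ip),
      pRPA = scale_track(data$tracks$shTop1$prpa)), active, ap)
    stats_df <- data.frame(
      track = names(grp),
      mean_dsb_pos = vapply(grp, `[[`, numeric(1), "mean_pos"),
      mean_dsb_neg = vapply(grp, `[[`, numeric(1), "mean_neg"),
      p_value = vapply(grp, `[[`, numeric(1), "p_value"))
    emit(write_tsv(stats_df, file.path(outdir, "dsb_group_stats.tsv")))
    emit(write_tsv(comp$table, file.path(outdir,
                                         "dsb_orientation_composition.tsv")))
    list(top25 = sco_s, classification = cl, composition = comp,
         group_stats = stats_df)
  })

  ## ---- report ----
  stage("report", function() {
    lines <- c("transcription-replication conflict pipeline summary",
               paste0("seed: ", cfg$seed),
               paste0("genes: ", nrow(genes), " (", nrow(active),
                      " active, RPKM > 0)"),
               paste0("initiation zones: ", nrow(repl$zones)),
               paste0("DRIP peaks: ",
                      paste(vapply(peaks$peaks, nrow, numeric(1)),
                            collapse = " / ")),
               paste0("converging pairs: ",
                      sum(confl$pairs$relation == "converging")),
               if (!is.null(dsb))
                 paste0("DSB+ genes: ",
                        sum(dsb$classification$labels == "DSB+")))
    writeLines(lines, emit(file.path(outdir, "summary.txt")))
    jsonlite::write_json(as.list(manifest),
                         file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE)
    NULL
  })
  say("pipeline complete: ", length(manifest), " files in ", outdir)
  invisible(list(data = data, replication = repl, peaks = peaks,
                 profiles = prof, conflicts = confl, dsb = dsb,
                 manifest = manifest))
}

# orientation of each gene's TTS from pair geometry alone: a gene whose TTS
# faces the neighbor head-to-head is converging (HO at TTS), a gene followed
# codirectionally is CD; anything else is left uncalled
truth_free_orientation <- function(pairs, genes) {
  ori <- stats::setNames(rep(NA_character_, nrow(genes)), genes$gene_id)
  conv <- pairs[pairs$relation == "converging", ]
  ori[c(conv$gene_a, conv$gene_b)] <- "HO"
  cod <- pairs[pairs$relation == "codirectional", ]
  ori[is.na(ori) & names(ori) %in% c(cod$gene_a, cod$gene_b)] <- "CD"
  ori[!is.na(ori)]
}

#' Command-line entry point
#'
#' `Rscript -e 'trconflict::pipeline_main()' -- --config cfg.json --outdir out`
#' Subcommand (positional, default `all`) selects which stage's outputs are
#' required; dependencies are always satisfied (from cache when `--resume`).
#'
#' @param args character vector of CLI arguments (defaults to the process
#'   arguments).
#' @return exit status 0 on success (invisibly); errors exit non-zero under
#'   Rscript.
#' @export
pipeline_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  opt_list <- list(
    optparse::make_option("--config", type = "character"),
    optparse::make_option("--outdir", type = "character", default = "trc_out"),
    optparse::make_option("--seed", type = "integer", default = NULL),
    optparse::make_option("--resume", action = "store_true", default = FALSE),
    optparse::make_option("--log-level", type = "character",
                          default = "info", dest = "log_level"))
  parsed <- optparse::parse_args(
    optparse::OptionParser(option_list = opt_list), args = args,
    positional_arguments = TRUE)
  sub <- if (length(parsed$args)) parsed$args[1] else "all"
  known <- c("all", "simulate", "rfd", "callpeaks", "annotate", "profile",
             "conflicts", "dsb", "report")
  if (!sub %in% known) stop("unknown subcommand: ", sub)
  o <- parsed$options
  if (is.null(o$config)) stop("--config is required")
  run_pipeline(o$config, o$outdir, seed = o$seed, resume = o$resume,
               log_level = o$log_level)
  invisible(0L)
}
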