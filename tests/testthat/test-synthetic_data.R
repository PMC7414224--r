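test_that("generator is deterministic under a fixed seed", {
  cfg <- small_sim_config(seed = 42)
  a <- simulate_experiment(cfg)
  b <- simulate_experiment(cfg)
  expect_identical(a$truth$origins, b$truth$origins)
  expect_identical(a$truth$rfd_true, b$truth$rfd_true)
  expect_identical(a$truth$dsb_positive, b$truth$dsb_positive)
  expect_identical(a$okseq$watson, b$okseq$watson)
  for (tr in names(a$tracks$shTop1))
    expect_identical(a$tracks$shTop1[[tr]]$values,
                     b$tracks$shTop1[[tr]]$values)
})

test_that("a single always-firing origin forces a deterministic RFD field", {
  cfg <- list(chrom_length = 1e6, bin_size = 1000, n_cells = 10)
  org <- data.frame(position = 5e5, efficiency = 1.0)
  r <- trconflict:::rfd_field(org, cfg)
  expect_true(all(r[1:499] == -1))
  expect_true(all(r[502:1000] == 1))
})

test_that("OK-seq sampling respects the strand model", {
  sim <- simulate_genome(small_sim_config(seed = 3))
  truth <- sim$truth
  # force extreme and neutral RFD bins, then check the binomial strand split
  truth$rfd_true$chrS[] <- 1
  ok <- simulate_okseq(truth, depth = 200)
  expect_true(all(ok$watson$chrS == 0))
  expect_true(mean(ok$crick$chrS) > 150)

  truth$rfd_true$chrS[] <- 0
  ok0 <- simulate_okseq(truth, depth = 1000)
  frac <- ok0$crick$chrS / pmax(ok0$crick$chrS + ok0$watson$chrS, 1)
  # binomial tail bound: per-bin crick fraction within [0.45, 0.55] with
  # >= 99% probability at depth 1000
  expect_gt(mean(frac >= 0.45 & frac <= 0.55), 0.97)

  okz <- simulate_okseq(truth, depth = 0)
  expect_true(all(okz$crick$chrS == 0) && all(okz$watson$chrS == 0))
})

test_that("RFD estimator converges to the planted field", {
  sim <- simulate_genome(small_sim_config(seed = 5, okseq_depth = 500))
  ok <- simulate_okseq(sim$truth)
  est <- compute_rfd(ok)$values$chrS
  rt <- sim$truth$rfd_true$chrS
  ok_bins <- !is.na(est)
  expect_gt(mean(ok_bins), 0.99)
  expect_lt(mean(abs(est[ok_bins] - rt[ok_bins])), 0.05)
})

test_that("planted structure sits where the truth says and nowhere else", {
  sim <- simulate_experiment(small_sim_config(seed = 7))
  truth <- sim$truth
  b <- truth$config$bin_size
  # every planted DRIP bump center is within one bin of a TSS/TTS anchor
  for (kind in c("TSS", "TTS")) {
    a <- anchor_of(sim$genes, kind)
    tab <- truth$planted_drip[truth$planted_drip$anchor == kind, ]
    pos <- a$position[match(tab$gene_id, a$gene_id)]
    expect_true(all(abs(tab$center - pos) <= b))
  }
  # zero-expression genes carry no planted bump
  silent <- sim$genes$gene_id[sim$genes$expression_rpkm == 0]
  expect_false(any(silent %in% truth$planted_drip$gene_id))
  expect_false(any(silent %in% truth$planted_prpa$gene_id))
  # head-on TTS fraction recorded and positive
  expect_gt(mean(truth$orientation_tts == "HO"), 0)
  # DSB+ labels are a subset of active genes
  expect_true(all(truth$dsb_positive %in% truth$active))

  # control condition: break tracks are background only -- their upper
  # quantile stays at the Poisson background level
  cfg <- truth$config
  for (nm in c("ibless", "gh2ax")) {
    v <- sim$tracks$control[[nm]]$values$chrS
    bg <- if (nm == "ibless") cfg$ibless_bg else cfg$gh2ax_bg
    expect_lt(stats::quantile(v, 0.999), stats::qpois(0.9999, bg) + 1)
  }
  # shTop1 i-BLESS signal confined to DSB+ TTS windows
  dsb_tts <- anchor_of(sim$genes[sim$genes$gene_id %in% truth$dsb_positive, ],
                       "TTS")$position
  v <- sim$tracks$shTop1$ibless$values$chrS
  centers <- (seq_along(v) - 0.5) * b
  inside <- vapply(centers, function(p) any(abs(dsb_tts - p) <= 2000 + b),
                   logical(1))
  expect_lt(stats::quantile(v[!inside], 0.999),
            stats::qpois(0.9999, cfg$ibless_bg) + 1)
  expect_gt(mean(v[inside]), cfg$ibless_amp / 2)
})

test_that("infeasible gene packing is an explicit error", {
  expect_error(simulate_genome(sim_config(chrom_length = 1e6, bin_size = 1000,
                                          n_genes = 500)),
               "infeasible packing")
})

test_that("write_simulation emits the declared plain-text files", {
  sim <- simulate_experiment(small_sim_config(seed = 2))
  dir <- withr::local_tempdir()
  files <- write_simulation(sim, dir)
  expect_true(all(file.exists(files)))
  back <- read_gene_annotation(file.path(dir, "genes.bed"),
                               layout = read_chrom_sizes(
                                 file.path(dir, "chrom.sizes")),
                               score_is_expression = TRUE)
  expect_equal(back$start, sim$genes$start)
  expect_equal(back$expression_rpkm, sim$genes$expression_rpkm,
               tolerance = 1e-12)
  okback <- read_okseq(file.path(dir, "okseq.tsv"), sim$layout, 1000)
  expect_identical(okback$crick$chrS, as.numeric(sim$okseq$crick$chrS))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(sort(truth$dsb_positive), sim$truth$dsb_positive)
})
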