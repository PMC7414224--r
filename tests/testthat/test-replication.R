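mk_counts <- function(W, C, bin = 1000) {
  lay <- genome_layout("c1", length(W) * bin)
  stranded_bin_counts(lay, bin, W, C)
}

test_that("RFD closed forms, masking, and antisymmetry", {
  cnt <- mk_counts(c(10, 0, 40), c(30, 0, 10))
  r <- compute_rfd(cnt, conflict_params(min_coverage = 30))
  expect_equal(r$values$c1, c(0.5, NA, -0.6))
  # W <-> C swap negates RFD exactly
  set.seed(6)
  W <- stats::rpois(200, 50); C <- stats::rpois(200, 50)
  a <- compute_rfd(mk_counts(W, C), conflict_params(min_coverage = 1))
  b <- compute_rfd(mk_counts(C, W), conflict_params(min_coverage = 1))
  expect_equal(a$values$c1, -b$values$c1)
})

test_that("initiation zones found at ascending strand switches only", {
  # hard step -1 -> +1 at bin 50 (position 50 kb)
  v <- c(rep(-1, 50), rep(1, 50))
  cnt <- mk_counts(ifelse(v < 0, 100, 0), ifelse(v < 0, 0, 100))
  z <- detect_initiation_zones(compute_rfd(cnt), conflict_params())
  expect_equal(nrow(z), 1)
  expect_lt(abs(z$center - 50000), 3000)
  expect_gt(z$efficiency, 0.5)

  flat <- mk_counts(rep(50, 100), rep(50, 100))
  expect_equal(nrow(detect_initiation_zones(compute_rfd(flat))), 0)

  # the negated track has a termination switch there, not an initiation zone
  neg <- detect_initiation_zones(
    compute_rfd(mk_counts(ifelse(v < 0, 0, 100), ifelse(v < 0, 100, 0))))
  expect_equal(nrow(neg), 0)
})

test_that("zones of a simulated genome avoid termination midpoints", {
  sim <- simulate_genome(small_sim_config(seed = 13))
  rfd <- compute_rfd(simulate_okseq(sim$truth))
  z <- detect_initiation_zones(rfd)
  zn <- detect_initiation_zones(structure(
    list(layout = rfd$layout, bin_size = rfd$bin_size,
         values = lapply(rfd$values, function(x) -x), flavor = "ratio"),
    class = class(rfd)))
  # no negated-track zone center falls inside an original zone
  if (nrow(zn) && nrow(z)) {
    inside <- vapply(zn$center, function(p)
      any(p >= z$start & p < z$end), logical(1))
    expect_false(any(inside))
  }
  expect_gt(nrow(z), 0)
})

test_that("orientation calls follow the signed codirectional convention", {
  v <- rep(-0.6, 10)
  cnt <- mk_counts(round(100 * (1 - v) / 2), round(100 * (1 + v) / 2))
  rfd <- compute_rfd(cnt)
  g <- gene_table(c("p", "m"), "c1", c(2000, 2000), c(8000, 8000),
                  c("+", "-"))
  ori <- orientation_at(g, "TTS", rfd)
  expect_equal(ori$orientation[ori$gene_id == "p"], "HO")
  expect_equal(ori$orientation[ori$gene_id == "m"], "CD")
  # masked anchor bin -> ambiguous with the flag set
  cnt0 <- mk_counts(rep(0, 10), rep(0, 10))
  ori0 <- orientation_at(g, "TTS", compute_rfd(cnt0))
  expect_true(all(ori0$orientation == "ambiguous"))
  expect_true(all(ori0$masked))
  # sub-threshold signal -> ambiguous without the mask flag
  vw <- rep(-0.1, 10)
  cw <- mk_counts(round(1000 * (1 - vw) / 2), round(1000 * (1 + vw) / 2))
  oriw <- orientation_at(g, "TTS", compute_rfd(cw))
  expect_true(all(oriw$orientation == "ambiguous"))
  expect_false(any(oriw$masked))
})

test_that("downstream origin distance respects transcription direction", {
  zones <- data.frame(chrom = "c1", start = c(7000, 14000),
                      end = c(9000, 16000), center = c(8000, 15000),
                      efficiency = 0.5)
  gp <- gene_table("p", "c1", 2000, 10001, "+")  # TTS at 10,000
  gm <- gene_table("m", "c1", 10000, 20000, "-") # TTS at 10,000
  expect_equal(distance_to_downstream_origin(gp, zones), 5000)
  expect_equal(distance_to_downstream_origin(gm, zones), 2000)
  none <- gene_table("x", "c1", 16000, 20000, "+")
  expect_true(is.na(distance_to_downstream_origin(none, zones)))
})

test_that("okseq text round-trip preserves counts", {
  set.seed(21)
  cnt <- mk_counts(stats::rpois(40, 20), stats::rpois(40, 20))
  f <- withr::local_tempfile()
  write_okseq(cnt, f)
  back <- read_okseq(f, cnt$layout, cnt$bin_size)
  expect_equal(back$watson$c1, as.numeric(cnt$watson$c1))
  expect_equal(back$crick$c1, as.numeric(cnt$crick$c1))
})
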