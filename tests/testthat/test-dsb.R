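test_that("top-fraction ranking sizes and the degenerate all-zero path", {
  n <- 100
  g <- gene_table(sprintf("g%03d", 1:n), "c1",
                  seq(5000, by = 9000, length.out = n),
                  seq(5000, by = 9000, length.out = n) + 6000, "+", 1)
  lay <- genome_layout("c1", 1e6)
  set.seed(2)
  tr <- signal_track(lay, 1000, stats::rpois(1000, 3), flavor = "raw")
  rk <- rank_tts_dsb(tr, g)
  expect_equal(length(rk$top_ids), 25)
  expect_false(rk$degenerate)
  expect_equal(rk$scores$gene_id[1], rk$top_ids[1])
  expect_true(all(diff(rk$scores$score) <= 1e-12))

  z <- signal_track(lay, 1000, numeric(1000), flavor = "raw")
  rz <- rank_tts_dsb(z, g)
  expect_true(rz$degenerate)
  expect_equal(length(rz$top_ids), 25)
  expect_equal(rz$top_ids, sort(g$gene_id)[1:25])  # tie-break by id
})

test_that("clustering recovers separated groups and is permutation-safe", {
  set.seed(5)
  n <- 60
  truth_pos <- sample(c(rep(TRUE, 20), rep(FALSE, 40)))
  f <- cbind(control = stats::rnorm(n, 1, 0.2),
             shTop1 = ifelse(truth_pos, stats::rnorm(n, 8, 0.4),
                             stats::rnorm(n, 1, 0.2)))
  rownames(f) <- sprintf("g%02d", 1:n)
  cl <- cluster_dsb_genes(f)
  expect_equal(unname(cl$labels == "DSB+"), truth_pos)
  # label assignment invariant under row permutation
  perm <- sample.int(n)
  cl2 <- cluster_dsb_genes(f[perm, ])
  expect_equal(cl2$labels[rownames(f)], cl$labels)
  # degenerate identical features
  fid <- matrix(1, 10, 2, dimnames = list(letters[1:10], c("a", "b")))
  expect_warning(cld <- cluster_dsb_genes(fid), "degenerate")
  expect_true(all(cld$labels == "DSB-"))
  expect_true(cld$degenerate)
})

test_that("rank-sum test: symmetry, power, and the exact oracle", {
  x <- c(1.2, 3.4, 2.2, 5.5, 0.1, 4.4)
  expect_gt(compare_groups(x, x)$p_value, 0.9)
  set.seed(7)
  a <- stats::rnorm(50); b <- stats::rnorm(50) + 10
  expect_lt(compare_groups(a, b)$p_value, 1e-6)
  expect_error(compare_groups(numeric(0), 1), "non-empty")

  # agreement with stats::wilcox.test (normal approximation, corrected)
  for (i in 1:10) {
    a <- stats::rnorm(15); b <- stats::rnorm(12) + stats::runif(1, -1, 1)
    ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
    got <- compare_groups(a, b)
    expect_equal(got$p_value, unname(ref$p.value), tolerance = 1e-10)
    expect_equal(got$statistic, unname(ref$statistic))
  }
  # exhaustive-enumeration oracle at small n, including ties
  set.seed(11)
  for (i in 1:15) {
    a <- sample(1:6, 7, replace = TRUE) + stats::runif(7, 0, 0.01)
    b <- sample(1:6, 8, replace = TRUE) + stats::runif(8, 0, 0.01)
    expect_lt(abs(compare_groups(a, b)$p_value - oracle_ranksum_exact(a, b)),
              0.05)
  }
})

test_that("orientation composition tables and the trivial all-HO case", {
  lab <- stats::setNames(c("DSB+", "DSB+", "DSB-", "DSB-"),
                         c("a", "b", "c", "d"))
  ori <- stats::setNames(rep("HO", 4), c("a", "b", "c", "d"))
  out <- orientation_composition(list(labels = lab), ori)
  expect_equal(out$table$pct_HO, c(100, 100))
  expect_equal(out$p_value, 1)
  ori2 <- stats::setNames(c("HO", "HO", "CD", "CD"), c("a", "b", "c", "d"))
  out2 <- orientation_composition(list(labels = lab), ori2)
  expect_equal(out2$table$pct_HO, c(100, 0))
  expect_lt(out2$p_value, 0.05)
})

test_that("duplicate groups give p ~ 1 in group profiles", {
  sim <- simulate_experiment(small_sim_config(seed = 37))
  act <- filter_active(sim$genes)
  lab <- stats::setNames(rep(c("DSB+", "DSB-"), length.out = nrow(act)),
                         act$gene_id)
  # interleaved labels on the same score distribution: no group difference
  gs <- group_signal_profiles(list(labels = lab),
                              list(ib = scale_track(
                                sim$tracks$control$ibless)), act)
  expect_gt(gs$ib$p_value, 0.01)
  expect_s3_class(gs$ib$profile_pos, "meta_profile")
})
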