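test_that("Poisson tail p-values match an independent summation oracle", {
  # P(X >= 50 | lambda = 5) by direct summation of the density
  p_oracle <- 1 - sum(exp(-5) * 5^(0:49) / factorial(0:49))
  expect_lt(p_oracle, 1e-15)
  # a lone high bin over a flat input must be the caller's top bin
  lay <- genome_layout("c1", 1e5)
  ipv <- rep(5, 100); ipv[40:41] <- 50
  ip <- signal_track(lay, 1000, ipv, flavor = "raw")
  inp <- signal_track(lay, 1000, rep(5, 100), flavor = "raw")
  pk <- call_peaks(ip, inp)
  expect_equal(nrow(pk), 1)
  expect_true(pk$start <= 39000 && pk$end >= 41000)
  expect_lt(pk$q_value, 1e-10)
  expect_true(pk$summit >= pk$start && pk$summit < pk$end)
})

test_that("all-zero tracks give an empty result, not an error", {
  z <- const_track(0, flavor = "raw")
  expect_equal(nrow(call_peaks(z, z)), 0)
})

test_that("BH q-values are monotone and bounded below by p", {
  set.seed(5)
  p <- stats::runif(500)^2
  q <- stats::p.adjust(p, "BH")
  expect_true(all(q >= p - 1e-12))
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))
})

test_that("reproducible_peaks keeps jittered matches and drops the rest", {
  pk <- data.frame(chrom = "c1", start = c(1000, 5000, 9000),
                   end = c(2000, 6400, 10000),
                   summit = c(1500, 5500, 9500), enrichment = 3,
                   q_value = 0.01)
  expect_equal(reproducible_peaks(list(pk, pk)), pk)
  far <- pk; far$start <- far$start + 50000; far$end <- far$end + 50000
  expect_equal(nrow(reproducible_peaks(list(pk, far))), 0)
  # jitter by < 25% of width keeps every peak (>= 50% reciprocal overlap)
  jit <- pk
  shift <- round(0.2 * (pk$end - pk$start))
  jit$start <- jit$start + shift; jit$end <- jit$end + shift
  cons <- reproducible_peaks(list(pk, jit, pk))
  expect_equal(nrow(cons), 3)
  expect_true(all(cons$start >= pk$start & cons$end <= jit$end))
  expect_error(reproducible_peaks(list(pk)), "at least 2")
})

test_that("summit annotation uses the priority and fractions sum to 1", {
  lay <- genome_layout("c1", 1e6)
  g <- gene_table(c("plus", "minus"), "c1", c(100000, 500000),
                  c(120000, 520000), c("+", "-"), c(1, 1), layout = lay)
  mkpk <- function(summit) data.frame(chrom = "c1", start = summit - 200,
                                      end = summit + 200, summit = summit,
                                      enrichment = 2, q_value = 0.01)
  ann <- annotate_peaks(rbind(mkpk(99000),   # 1 kb upstream of + TSS
                              mkpk(122000),  # 2 kb past + TTS
                              mkpk(110000),  # + gene body
                              mkpk(800000)), # desert
                        g, lay)
  expect_equal(as.character(ann$categories),
               c("TSS_region", "TTS_region", "gene_body", "intergenic"))
  expect_equal(sum(ann$fractions), 1)
  expect_equal(sum(ann$baseline), 1)
  # the - gene mirrors: 1 kb upstream of its TSS is at 521,000
  ann2 <- annotate_peaks(mkpk(521000), g, lay)
  expect_equal(as.character(ann2$categories), "TSS_region")
})

test_that("gene/peak overlap percentages", {
  g <- gene_table(paste0("g", 1:4), "c1", c(0, 1e4, 2e4, 3e4) + 1000,
                  c(0, 1e4, 2e4, 3e4) + 6000, "+", 1)
  pkA <- data.frame(chrom = "c1", start = c(2000, 12000),
                    end = c(3000, 13000), summit = c(2500, 12500),
                    enrichment = 2, q_value = 0.01)
  pkB <- pkA[1, ]
  ov <- gene_peak_overlap(g, list(A = pkA, B = pkB))
  expect_equal(unname(colSums(ov$labels)), c(2, 1))
  # B subset of A: |A&B|/|B| = 100
  expect_equal(ov$pairwise$pct_of_b, 100)
  expect_equal(ov$pairwise$pct_of_a, 50)
})

test_that("broad domain widths merge runs and respect gaps", {
  v <- numeric(200)
  v[11:40] <- 5               # one 30-bin run
  v[100:104] <- 5; v[110:114] <- 5  # two runs split by a 5-bin gap
  tr <- signal_track(genome_layout("c1", 2e5), 1000, v, flavor = "ratio")
  d1 <- broad_domain_width(tr, threshold = 1, merge_gap = 1)
  expect_equal(d1$width[1], 30000)
  expect_equal(nrow(d1), 3)
  d2 <- broad_domain_width(tr, threshold = 1, merge_gap = 6)
  expect_equal(nrow(d2), 2)
})

test_that("null peak-caller calibration over seeds", {
  lay <- genome_layout("c1", 5e6)
  n_with_peaks <- 0
  for (s in 1:10) {
    set.seed(s)
    ip <- signal_track(lay, 1000, stats::rpois(5000, 5), flavor = "raw")
    inp <- signal_track(lay, 1000, stats::rpois(5000, 5), flavor = "raw")
    if (nrow(call_peaks(ip, inp)) > 0) n_with_peaks <- n_with_peaks + 1
  }
  expect_lte(n_with_peaks, 1)
})
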