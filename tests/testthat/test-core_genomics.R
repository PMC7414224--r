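test_that("gene annotation reading maps BED fields and rejects bad rows", {
  bed <- withr::local_tempfile(lines = c(
    "chr1\t1000\t5000\tgeneA\t0\t+",
    "chr1\t7000\t9000\tgeneB\t3.5\t-"))
  g <- read_gene_annotation(bed, score_is_expression = TRUE)
  expect_s3_class(g, "gene_table")
  expect_equal(g$start, c(1000, 7000))
  expect_equal(g$end, c(5000, 9000))
  expect_equal(g$strand, c("+", "-"))
  expect_equal(g$expression_rpkm, c(0, 3.5))

  empty <- withr::local_tempfile(lines = character())
  expect_equal(nrow(read_gene_annotation(empty)), 0)

  bad <- withr::local_tempfile(lines = "chr1\t5000\t1000\tg\t0\t+")
  expect_error(read_gene_annotation(bad), "line 1")
  badstrand <- withr::local_tempfile(lines = "chr1\t0\t10\tg\t0\t*")
  expect_error(read_gene_annotation(badstrand), "strand")
  # coordinates past the chromosome end are rejected when a layout is given
  expect_error(read_gene_annotation(bed, layout = genome_layout("chr1", 6000)),
               "past")
})

test_that("anchors follow the strand convention and swap under reflection", {
  g <- gene_table(c("a", "b"), "c1", c(1000, 1000), c(5000, 5000),
                  c("+", "-"))
  expect_equal(anchor_of(g, "TSS")$position, c(1000, 4999))
  expect_equal(anchor_of(g, "TTS")$position, c(4999, 1000))

  # reflecting an interval about its midpoint and flipping strand swaps
  # TSS and TTS positions
  set.seed(4)
  for (i in 1:25) {
    s <- sample.int(1e5, 1); e <- s + sample.int(5e3, 1)
    st <- sample(c("+", "-"), 1)
    g1 <- gene_table("g", "c1", s, e, st)
    g2 <- gene_table("g", "c1", s, e, setdiff(c("+", "-"), st))
    refl <- function(p) (s + e - 1) - p  # midpoint reflection of a base
    expect_equal(anchor_of(g2, "TSS")$position,
                 refl(anchor_of(g1, "TSS")$position))
    expect_equal(anchor_of(g2, "TTS")$position,
                 refl(anchor_of(g1, "TTS")$position))
  }
})

test_that("overlap_query matches the all-pairs oracle and edge cases", {
  q <- data.frame(chrom = "c1", start = 0, end = 10)
  s <- data.frame(chrom = "c1", start = 10, end = 20)
  expect_equal(nrow(overlap_query(q, s)), 0)  # half-open touching
  expect_equal(nrow(overlap_query(q[0, ], s)), 0)
  expect_error(overlap_query(q, s, layout = genome_layout("other", 100)),
               "unknown chromosome")

  set.seed(11)
  for (i in 1:20) {
    qq <- random_intervals(60, chroms = c("c1", "c2"))
    ss <- random_intervals(60, chroms = c("c1", "c2"))
    expect_equal(overlap_query(qq, ss), oracle_overlaps(qq, ss))
  }
})

test_that("bedGraph round-trip is bit-exact and malformed input errors", {
  lay <- genome_layout("c1", 100000)
  set.seed(2)
  tr <- signal_track(lay, 1000, stats::runif(100) * 7, flavor = "ratio")
  f <- withr::local_tempfile()
  write_bedgraph(tr, f)
  back <- read_bedgraph(f, lay, 1000)
  expect_identical(back$values$c1, tr$values$c1)

  one <- withr::local_tempfile(lines = "c1\t0\t1000\t2.5")
  expect_equal(read_bedgraph(one, lay, 1000)$values$c1[1], 2.5)

  overl <- withr::local_tempfile(lines = c("c1\t0\t1000\t1", "c1\t500\t1500\t2"))
  expect_error(read_bedgraph(overl, lay, 1000), "overlapping")
  unsort <- withr::local_tempfile(lines = c("c1\t2000\t3000\t1", "c1\t0\t1000\t2"))
  expect_error(read_bedgraph(unsort, lay, 1000), "unsorted")
  expect_equal(read_bedgraph(unsort, lay, 1000, sort = TRUE)$values$c1[1], 2)
})

test_that("chrom sizes round-trip and layout invariants hold", {
  expect_error(genome_layout(c("a", "a"), c(1, 2)), "unique")
  expect_error(genome_layout("a", 0), "> 0")
  f <- withr::local_tempfile()
  write_chrom_sizes(genome_layout(c("c1", "c2"), c(5e6, 2e6)), f)
  lay <- read_chrom_sizes(f)
  expect_equal(lay$chroms, c("c1", "c2"))
  expect_equal(unname(lay$lengths), c(5e6, 2e6))
})
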