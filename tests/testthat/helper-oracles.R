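# independent brute-force oracles and small fixtures shared across tests

# all-pairs double-loop overlap oracle (half-open semantics), vectorized
# over the outer product so 500x500 instances stay fast
oracle_overlaps <- function(query, subject) {
  hit <- outer(query$chrom, subject$chrom, "==") &
    outer(query$start, subject$end, "<") &
    outer(query$end, subject$start, ">")
  idx <- which(hit, arr.ind = TRUE)
  res <- data.frame(query = idx[, 1], subject = idx[, 2])
  res <- res[order(res$query, res$subject), , drop = FALSE]
  rownames(res) <- NULL
  res
}

random_intervals <- function(n, chroms = "c1", max_pos = 10000) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1
  data.frame(chrom = sample(chroms, n, replace = TRUE), start = start,
             end = start + sample.int(200, n, replace = TRUE))
}

# exact two-sided rank-sum p-value by exhaustive enumeration of group
# assignments (feasible for n + m <= 16)
oracle_ranksum_exact <- function(a, b) {
  n <- length(a); m <- length(b)
  pool <- c(a, b)
  r <- rank(pool)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  cmb <- utils::combn(n + m, n)
  us <- apply(cmb, 2, function(ix) sum(r[ix]) - n * (n + 1) / 2)
  mean(abs(us - n * m / 2) >= abs(u_obs - n * m / 2))
}

# exhaustive adjacent-pair classification oracle
oracle_pairs <- function(genes) {
  out <- list()
  for (ch in unique(genes$chrom)) {
    g <- genes[genes$chrom == ch, ]
    g <- g[order(g$start, g$end, g$gene_id), ]
    for (i in seq_len(max(nrow(g) - 1, 0))) {
      a <- g[i, ]; b <- g[i + 1, ]
      rel <- if (a$strand == b$strand) "codirectional" else
        if (a$strand == "+") "converging" else "divergent"
      out[[length(out) + 1]] <- data.frame(
        gene_a = a$gene_id, gene_b = b$gene_id, chrom = ch, relation = rel,
        gap = max(b$start - a$end, 0))
    }
  }
  do.call(rbind, out)
}

# small, fast simulated world for unit tests (distinct from the default
# acceptance-scale genome)
small_sim_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(seed = seed, chrom_length = 3e6, n_genes = 250, n_cells = 100,
         okseq_depth = 300),
    list(...))
  do.call(sim_config, args)
}

# lazily built, shared across test files needing the default world
.sim_cache <- new.env(parent = emptyenv())
default_sim <- function(seed = 1) {
  key <- paste0("s", seed)
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- simulate_experiment(sim_config(seed = seed))
  .sim_cache[[key]]
}

tiny_layout <- function(len = 1e5, chrom = "c1") genome_layout(chrom, len)

const_track <- function(value, nbins = 100, bin = 1000, flavor = "ratio",
                        chrom = "c1") {
  lay <- genome_layout(chrom, nbins * bin)
  signal_track(lay, bin, rep(value, nbins), flavor = flavor)
}
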