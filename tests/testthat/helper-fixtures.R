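# Shared fixture builders and independent oracles.

# A small deterministic gene set on one chromosome.
toy_genes <- function() {
  tibble::tibble(
    gene_id = c("gA", "gB", "gC"),
    chrom = "chrI",
    start = c(2000L, 8000L, 14000L),
    end = c(5000L, 11000L, 16000L),
    strand = c("+", "-", "+"))
}

# Random non-overlapping genes plus uniform random probes for oracle tests.
random_instance <- function(n_genes, n_probes, flank_bp = 300) {
  len <- sample(800:3000, n_genes, replace = TRUE)
  gap <- sample((2 * flank_bp + 100):2500, n_genes, replace = TRUE)
  start <- cumsum(gap) + cumsum(c(0, head(len, -1)))
  genes <- tibble::tibble(
    gene_id = sprintf("g%03d", seq_len(n_genes)),
    chrom = "chrI",
    start = as.integer(start),
    end = as.integer(start + len),
    strand = sample(c("+", "-"), n_genes, replace = TRUE))
  span <- max(genes$end) + 2000
  pstart <- sort(sample.int(span, n_probes, replace = TRUE))
  probes <- tibble::tibble(
    chrom = "chrI", start = pstart, end = pstart + 50L,
    value = rnorm(n_probes))
  list(genes = genes, probes = probes)
}

# Exhaustive per-probe loop over genes and bins: the binning oracle.
oracle_profile <- function(assignments, n_bins, gene_ids) {
  vals <- matrix(NA_real_, length(gene_ids), n_bins,
                 dimnames = list(gene_ids, NULL))
  per_gene <- split(assignments[c("x", "value")], assignments$gene_id)
  for (gid in intersect(gene_ids, names(per_gene))) {
    a <- per_gene[[gid]]
    for (j in seq_len(n_bins)) {
      lo <- (j - 1) / n_bins
      hi <- j / n_bins
      sel <- a$x >= lo & (a$x < hi | (j == n_bins & a$x <= 1))
      if (any(sel)) vals[gid, j] <- mean(a$value[sel])
    }
  }
  vals
}

# Upper hypergeometric tail by direct combinatorial summation.
oracle_hyper_tail <- function(k, K, n, N) {
  js <- k:min(n, K)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Difference-profile fixture: two conditions over one gene layout.
sim_pair <- function(cfg, delta_mut, amp5_mut, seed_offset = 0) {
  genes <- simulate_genome(cfg)
  wt <- simulate_occupancy(genes, cfg, delta = 0,
                           seed = cfg$seed + 101 + seed_offset)
  mut <- simulate_occupancy(genes, cfg, delta = delta_mut, amp5 = amp5_mut,
                            seed = cfg$seed + 202 + seed_offset)
  list(genes = genes, wt = wt, mut = mut)
}
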