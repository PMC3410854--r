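#' Simulation settings for synthetic tiling-array data
#'
#' Bundles every knob of the generator. The defaults emulate the design
#' the analysis targets: probes every 200 bp across a gene-dense genome,
#' a 540-gene cohort in four occupancy classes, a 5'-biased occupancy
#' shape, a 3'-shift effect acting on the downstream half of the gene
#' body, and a companion chromatin mark whose gene-level baseline is
#' correlated with occupancy at rho = 0.58.
#'
#' @param n_genes number of genes to simulate.
#' @param gene_len_range integer `(min, max)` coding-region length in bp.
#' @param probe_spacing distance between probe starts, bp.
#' @param probe_len probe length, bp.
#' @param n_classes number of occupancy classes.
#' @param class_levels per-class baseline log2 enrichment (length
#'   `n_classes`, ascending).
#' @param level_sd within-class gene-to-gene baseline sd, log2 units.
#' @param shape_amp5 amplitude of the 5' occupancy bias (log2 units at
#'   the transcription start, decaying linearly to 0 at the 3' end).
#' @param shift_delta 3'-shift effect size, log2 units at the 3' end.
#' @param noise_sd per-probe Gaussian noise sd, log2 units.
#' @param mark_rho target gene-level correlation between occupancy and the
#'   companion mark, in `[-1, 1]`.
#' @param intergenic_gap integer `(min, max)` gap between genes, bp.
#' @param chrom_length optional fixed chromosome length budget, bp. When
#'   given, genes that do not fit raise an error; by default chromosomes
#'   grow to fit, up to 500 genes each.
#' @param seed RNG seed for genome layout.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_genes = 540,
                       gene_len_range = c(1200L, 3000L),
                       probe_spacing = 200L,
                       probe_len = 50L,
                       n_classes = 4L,
                       class_levels = c(0.4, 0.9, 1.5, 2.2),
                       level_sd = 0.2,
                       shape_amp5 = 0.4,
                       shift_delta = 0.3,
                       noise_sd = 0.25,
                       mark_rho = 0.58,
                       intergenic_gap = c(700L, 1400L),
                       chrom_length = NULL,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              gene_len_range = as.integer(gene_len_range),
              probe_spacing = as.integer(probe_spacing),
              probe_len = as.integer(probe_len),
              n_classes = as.integer(n_classes),
              class_levels = as.numeric(class_levels),
              level_sd = level_sd, shape_amp5 = shape_amp5,
              shift_delta = shift_delta, noise_sd = noise_sd,
              mark_rho = mark_rho,
              intergenic_gap = as.integer(intergenic_gap),
              chrom_length = chrom_length,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_genes < 0) abort("n_genes must be >= 0.")
  if (cfg$gene_len_range[1] > cfg$gene_len_range[2]) {
    abort("gene_len_range must satisfy min <= max.")
  }
  if (cfg$probe_spacing <= 0) abort("probe_spacing must be positive.")
  if (cfg$probe_len <= 0) abort("probe_len must be positive.")
  if (cfg$noise_sd < 0) abort("noise_sd must be >= 0.")
  if (abs(cfg$mark_rho) > 1) abort("mark_rho must lie in [-1, 1].")
  if (length(cfg$class_levels) != cfg$n_classes) {
    abort("class_levels must have one entry per class.")
  }
  invisible(cfg)
}

#' Simulate a non-overlapping gene layout
#'
#' Genes of uniform random length are packed left to right with random
#' intergenic gaps, random strand, round-robin occupancy class and a
#' per-gene baseline (`class level + Normal(0, level_sd)` in log2 units).
#' Chromosomes hold at most 500 genes and their lengths are recorded in
#' the `seqlengths` attribute. Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return tibble with `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `class`, `baseline`; attribute `seqlengths` is a named vector of
#'   chromosome lengths.
#' @export
simulate_genome <- function(config) {
  validate_sim_config(config)
  n <- config$n_genes
  if (n == 0) {
    out <- tibble(gene_id = character(), chrom = character(),
                  start = integer(), end = integer(), strand = character(),
                  class = integer(), baseline = double())
    attr(out, "seqlengths") <- setNames(integer(), character())
    return(out)
  }
  withr::with_seed(config$seed, {
    len <- sample(seq(config$gene_len_range[1], config$gene_len_range[2]),
                  n, replace = TRUE)
    gap <- sample(seq(config$intergenic_gap[1], config$intergenic_gap[2]),
                  n, replace = TRUE)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    jitter <- rnorm(n, 0, config$level_sd)
    per_chrom <- 500L
    chrom_idx <- (seq_len(n) - 1L) %/% per_chrom + 1L
    chrom <- paste0("chr", chrom_idx)
    start <- integer(n)
    pos <- 0L
    for (i in seq_len(n)) {
      if (i > 1 && chrom_idx[i] != chrom_idx[i - 1]) pos <- 0L
      pos <- pos + gap[i]
      start[i] <- pos
      pos <- pos + len[i]
    }
    end <- start + len
    seqlen <- vapply(split(end + config$intergenic_gap[2], chrom),
                     max, numeric(1))
    if (!is.null(config$chrom_length)) {
      if (any(seqlen > config$chrom_length)) {
        abort(sprintf(
          "cannot pack %d genes into chromosomes of %d bp: need up to %d bp",
          n, config$chrom_length, max(seqlen)))
      }
      seqlen[] <- config$chrom_length
    }
    cls <- ((seq_len(n) - 1L) %% config$n_classes) + 1L
    out <- tibble(gene_id = sprintf("g%04d", seq_len(n)),
                  chrom = chrom, start = start, end = end, strand = strand,
                  class = cls,
                  baseline = config$class_levels[cls] + jitter)
    attr(out, "seqlengths") <- setNames(as.integer(seqlen),
                                        names(seqlen))[unique(chrom)]
    out
  })
}

#' Expected log2 enrichment along the scaled gene body
#'
#' The generative occupancy shape:
#' `baseline + amp5 * (1 - x) + delta * max(0, 2x - 1)`,
#' where `x` in `[0, 1]` runs 5' to 3' along the coding region. `amp5`
#' produces the 5'-biased profile typical of average-gene occupancy
#' curves; `delta` adds a 3'-shift component that is zero on the 5' half
#' and grows linearly to `delta` at the 3' end.
#'
#' @param x scaled gene-body position(s) in `[0, 1]`.
#' @param class_level baseline log2 enrichment.
#' @param amp5 5'-bias amplitude.
#' @param delta 3'-shift effect size.
#' @return expected log2 enrichment, vectorized over `x`.
#' @export
occupancy_shape <- function(x, class_level, amp5, delta) {
  if (any(x < 0 | x > 1)) abort("scaled position x must lie in [0, 1].")
  class_level + amp5 * (1 - x) + delta * pmax(0, 2 * x - 1)
}

# Tile probes across every chromosome of a simulated genome.
tile_probes <- function(genes, config) {
  seqlen <- attr(genes, "seqlengths")
  if (is.null(seqlen)) {
    seqlen <- vapply(split(genes$end, genes$chrom), function(e)
      max(e) + config$intergenic_gap[2], numeric(1))
  }
  purrr::map2_dfr(names(seqlen), as.numeric(seqlen), function(ch, len) {
    starts <- seq(0L, max(0L, len - config$probe_len), by = config$probe_spacing)
    tibble(chrom = ch, start = as.integer(starts),
           end = as.integer(starts + config$probe_len))
  })
}

# Expected value of every probe given per-gene baselines and effect sizes.
probe_expectation <- function(probes, genes, amp5, delta) {
  mu <- numeric(nrow(probes))
  if (nrow(genes)) {
    mid <- (probes$start + probes$end) / 2
    hit <- match_probe_gene(probes$chrom, mid, genes, flank_bp = 0)
    in_gene <- !is.na(hit$gene)
    g <- hit$gene[in_gene]
    xg <- (mid[in_gene] - genes$start[g]) / (genes$end[g] - genes$start[g])
    xg <- ifelse(genes$strand[g] == "-", 1 - xg, xg)
    mu[in_gene] <- occupancy_shape(xg, genes$baseline[g], amp5, delta)
  }
  mu
}

# For each probe midpoint, the index of the gene whose [start-flank,
# end+flank) span contains it; ties in coding distance drop the probe.
match_probe_gene <- function(chrom, mid, genes, flank_bp) {
  pr <- GenomicRanges::GRanges(chrom,
          IRanges::IRanges(floor(mid) + 1L, width = 1L))
  ext <- GenomicRanges::GRanges(genes$chrom,
          IRanges::IRanges(pmax(genes$start - flank_bp, 0) + 1L,
                           genes$end + flank_bp))
  ov <- GenomicRanges::findOverlaps(pr, ext)
  pi <- S4Vectors::queryHits(ov)
  gi <- S4Vectors::subjectHits(ov)
  ok <- mid[pi] >= genes$start[gi] - flank_bp & mid[pi] < genes$end[gi] + flank_bp
  pi <- pi[ok]; gi <- gi[ok]
  gene <- rep(NA_integer_, length(mid))
  if (length(pi)) {
    d <- pmax(0, genes$start[gi] - mid[pi], mid[pi] - genes$end[gi])
    o <- order(pi, d)
    pi <- pi[o]; gi <- gi[o]; d <- d[o]
    first <- !duplicated(pi)
    gene[pi[first]] <- gi[first]
    # a midpoint equidistant from two coding regions is ambiguous: drop it
    if (any(!first)) {
      runs <- split(seq_along(pi), pi)
      amb <- vapply(runs, function(ix)
        length(ix) > 1 && d[ix[2]] == d[ix[1]], logical(1))
      gene[as.integer(names(runs))[amb]] <- NA_integer_
    }
  }
  list(gene = gene)
}

#' Simulate one condition's probe-level occupancy track
#'
#' Probes are tiled genome-wide every `probe_spacing` bp. A probe whose
#' midpoint lies inside a coding region draws
#' `Normal(occupancy_shape(x), noise_sd)` with `x` measured 5' to 3'
#' (minus-strand genes flipped); intergenic probes draw `Normal(0,
#' noise_sd)`. Deterministic given `seed`.
#'
#' @param genes gene tibble from [simulate_genome()].
#' @param config a [sim_config()].
#' @param delta 3'-shift effect for this condition (default
#'   `config$shift_delta`; use 0 for a wild-type-like condition).
#' @param amp5 5'-bias amplitude for this condition.
#' @param seed RNG seed for probe noise.
#' @return probe tibble `chrom`, `start`, `end`, `value`.
#' @export
simulate_occupancy <- function(genes, config, delta = config$shift_delta,
                               amp5 = config$shape_amp5,
                               seed = config$seed) {
  validate_sim_config(config)
  probes <- tile_probes(genes, config)
  mu <- probe_expectation(probes, genes, amp5, delta)
  withr::with_seed(seed, {
    probes$value <- mu + rnorm(nrow(probes), 0, config$noise_sd)
  })
  probes
}

#' Simulate a companion mark correlated at the gene level
#'
#' Draws a per-gene baseline for a second chromatin mark so that the
#' population correlation with the occupancy baselines equals
#' `config$mark_rho`, then tiles probes with the same shape machinery
#' (no 3'-shift component). With `mark_rho = 1` and `noise_sd = 0` the
#' mark is a deterministic affine copy of the occupancy baseline.
#'
#' @inheritParams simulate_occupancy
#' @return probe tibble `chrom`, `start`, `end`, `value`.
#' @export
simulate_correlated_mark <- function(genes, config, seed = config$seed) {
  validate_sim_config(config)
  rho <- config$mark_rho
  mu_b <- mean(config$class_levels)
  sd_b <- sqrt(mean((config$class_levels - mu_b)^2) + config$level_sd^2)
  withr::with_seed(seed, {
    z <- rnorm(nrow(genes))
    zb <- (genes$baseline - mu_b) / sd_b
    mark_base <- mu_b + sd_b * (rho * zb + sqrt(1 - rho^2) * z)
    mark_genes <- genes
    mark_genes$baseline <- mark_base
    probes <- tile_probes(genes, config)
    mu <- probe_expectation(probes, mark_genes, amp5 = config$shape_amp5,
                            delta = 0)
    probes$value <- mu + rnorm(nrow(probes), 0, config$noise_sd)
  })
  probes
}

#' Simulate a ChIP-qPCR replicate table
#'
#' Generates IP/input signal pairs per primer pair whose percent-input
#' recomputes to `truth * lognormal(cv)`: multiplicative noise with unit
#' mean and the stated coefficient of variation, mimicking independent
#' ChIP experiments.
#'
#' @param truth named numeric vector of true percent-input values per
#'   target (strictly positive).
#' @param cv fractional coefficient of variation of replicate noise.
#' @param n_reps replicates per target.
#' @param condition condition label for the table.
#' @param input_fraction fraction of chromatin used as input aliquot.
#' @param input_scale linear input signal level (arbitrary units).
#' @param seed RNG seed.
#' @return tibble with `target`, `condition`, `replicate`, `ip_signal`,
#'   `input_signal`, `input_fraction`.
#' @export
simulate_qpcr <- function(truth, cv = 0.15, n_reps = 3, condition = "wt",
                          input_fraction = 1, input_scale = 100,
                          seed = 1L) {
  if (any(truth <= 0)) abort("true percent-input values must be > 0.")
  if (cv < 0) abort("cv must be >= 0.")
  if (n_reps < 1) abort("n_reps must be >= 1.")
  targets <- names(truth) %||% paste0("amplicon", seq_along(truth))
  sdlog <- sqrt(log1p(cv^2))
  withr::with_seed(seed, {
    grid <- tidyr::expand_grid(target = targets,
                               replicate = seq_len(n_reps))
    noise <- exp(rnorm(nrow(grid), -sdlog^2 / 2, sdlog))
    tv <- unname(truth)[match(grid$target, targets)]
    tibble(target = grid$target, condition = condition,
           replicate = grid$replicate,
           ip_signal = (tv / 100) * (input_scale / input_fraction) * noise,
           input_signal = input_scale,
           input_fraction = input_fraction)
  })
}

#' Simulate a toy gene-category map
#'
#' Assigns each gene one category. One category ("rp-like", emulating a
#' functional class concentrated in the highest occupancy genes) is
#' preferentially drawn from the top occupancy class; the rest are
#' uniform filler categories, so downstream over-representation tests
#' have signal to find.
#'
#' @param genes tibble from [simulate_genome()].
#' @param n_filler number of uniform filler categories.
#' @param top_frac fraction of top-class genes put in the focal category.
#' @param seed RNG seed.
#' @return tibble with `gene_id`, `category`.
#' @export
simulate_categories <- function(genes, n_filler = 8, top_frac = 0.5,
                                seed = 1L) {
  withr::with_seed(seed, {
    top_class <- max(genes$class)
    focal <- genes$class == top_class & runif(nrow(genes)) < top_frac
    cat <- ifelse(focal, "rp-like",
                  paste0("cat", sample.int(n_filler, nrow(genes),
                                           replace = TRUE)))
    tibble(gene_id = genes$gene_id, category = cat)
  })
}
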