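test_that("scaled positions honor boundaries, strand and exclusion rules", {
  genes <- toy_genes()
  # midpoint exactly at a + gene's start, no flanks -> x = 0
  probes <- tibble::tibble(chrom = "chrI",
                           start = c(1975L, 4975L, 10974L, 7975L),
                           end = c(2025L, 5025L, 11024L, 8025L),
                           value = 1:4 / 10)
  asn <- assign_probes(genes, probes, flank_bp = 0)
  a <- asn[order(asn$gene_id, asn$x), ]
  # gA: probe 1 at start (x=0); probe 2 midpoint 5000 = end -> excluded
  expect_equal(a$x[a$gene_id == "gA"], 0)
  # gB is minus strand: probe at its last base (mid 10999) maps to x ~ 0,
  # probe at its genomic start (mid 8000) to x = 1
  xb <- a$x[a$gene_id == "gB"]
  expect_equal(sort(xb), c(1 - 2999 / 3000, 1))
  expect_lt(min(xb), 0.01)
  # one bp outside the span -> unassigned
  outside <- tibble::tibble(chrom = "chrI", start = 1949L, end = 1950L,
                            value = 9)
  expect_equal(nrow(assign_probes(genes, outside, flank_bp = 0)), 0)
  expect_error(assign_probes(genes, probes, flank_bp = -1), ">= 0")
})

test_that("flanked assignment maps flanks onto the layout's outer fractions", {
  genes <- toy_genes()[1, ]  # gA: 2000-5000, +
  probes <- tibble::tibble(chrom = "chrI",
                           start = c(1825L, 3475L, 5125L),
                           end = c(1875L, 3525L, 5175L), value = c(1, 2, 3))
  asn <- assign_probes(genes, probes, flank_bp = 300,
                       bin_layout = c(0.1, 0.8, 0.1))
  # mid 1850: 150/300 into the 5' flank -> x = 0.05
  # mid 3500: halfway through coding -> x = 0.1 + 0.8 * 0.5 = 0.5
  # mid 5150: 150/300 into the 3' flank -> x = 0.95
  expect_equal(sort(asn$x), c(0.05, 0.5, 0.95))
})

test_that("binning averages within bins and leaves empty bins missing", {
  asn <- tibble::tibble(gene_id = "g1", x = c(0.01, 0.015, 0.99),
                        value = c(1, 3, 7))
  attr(asn, "bin_layout") <- c(0, 1, 0)
  m <- build_profile_matrix(asn, n_bins = 2)
  expect_equal(unname(pm_values(m)[1, ]), c(2, 7))
  m10 <- build_profile_matrix(asn, n_bins = 10)
  expect_equal(unname(pm_values(m10)[1, 1]), 2)
  expect_true(all(is.na(pm_values(m10)[1, 2:9])))
  expect_equal(unname(pm_values(m10)[1, 10]), 7)
})

test_that("binning matches the exhaustive per-probe loop on random instances", {
  withr::local_seed(101)
  for (rep in 1:20) {
    inst <- random_instance(sample(3:20, 1), sample(50:500, 1))
    asn <- assign_probes(inst$genes, inst$probes, flank_bp = 300)
    n_bins <- sample(c(10, 25, 50), 1)
    m <- build_profile_matrix(asn, n_bins, gene_ids = inst$genes$gene_id)
    expect_equal(unname(pm_values(m)),
                 unname(oracle_profile(asn, n_bins, inst$genes$gene_id)),
                 tolerance = 1e-12)
  }
})

test_that("translation and strand-mirror leave profile matrices unchanged", {
  withr::local_seed(202)
  inst <- random_instance(10, 400)
  build <- function(genes, probes)
    pm_values(build_profile_matrix(assign_probes(genes, probes, 300), 50,
                                   gene_ids = sort(genes$gene_id)))
  base <- build(inst$genes, inst$probes)
  # shift everything by a constant
  shift <- function(df, k) dplyr::mutate(df, start = start + k, end = end + k)
  expect_equal(build(shift(inst$genes, 5000L), shift(inst$probes, 5000L)),
               base)
  # mirror the genome and flip strands
  G <- max(inst$genes$end, inst$probes$end) + 1000L
  mg <- dplyr::mutate(inst$genes, start2 = G - end, end2 = G - start,
                      start = start2, end = end2,
                      strand = ifelse(strand == "+", "-", "+"))
  mp <- dplyr::mutate(inst$probes, start2 = G - end, end2 = G - start,
                      start = start2, end = end2)
  expect_equal(build(mg[names(inst$genes)], mp[names(inst$probes)]), base)
})

test_that("total enrichment uses coding probes only and flags sparse genes", {
  genes <- toy_genes()[1, ]
  probes <- tibble::tibble(
    chrom = "chrI",
    start = c(2475L, 3475L, 1875L),  # two coding, one flank
    end = c(2525L, 3525L, 1925L),
    value = c(0.5, 1.5, 9))
  tot <- gene_total_enrichment(genes, probes, min_probes = 2)
  expect_equal(tot$total_enrichment, 1.0)
  expect_equal(tot$n_probes, 2L)
  expect_true(tot$assigned)
  expect_false(gene_total_enrichment(genes, probes, min_probes = 5)$assigned)
  none <- gene_total_enrichment(genes, probes[3, ], min_probes = 1)
  expect_equal(none$n_probes, 0L)
  expect_false(none$assigned)
})

test_that("quartile grouping splits evenly, by reference, with stable ties", {
  summaries <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:8),
    total_enrichment = c(1, 2, 3, 4, 5, 6, 7, 8),
    n_probes = 10L, assigned = TRUE)
  grp <- group_by_quartile(summaries)
  expect_equal(as.vector(table(grp$quartile)), rep(2, 4))
  expect_equal(as.character(grp$quartile[grp$gene_id == "g01"]), "Q1")
  expect_equal(as.character(grp$quartile[grp$gene_id == "g08"]), "Q4")

  # mutant labeled by wild-type reference, not its own totals
  mutant <- dplyr::mutate(summaries, total_enrichment = rev(total_enrichment))
  grp_mut <- group_by_quartile(mutant, reference = summaries)
  expect_equal(grp_mut$quartile, grp$quartile)

  # ties broken deterministically by gene_id
  tied <- dplyr::mutate(summaries, total_enrichment = c(1, 1, 1, 1, 2, 2, 2, 2))
  grp_tied <- group_by_quartile(tied)
  expect_equal(as.character(grp_tied$quartile[grp_tied$gene_id %in%
                                                c("g01", "g02")]),
               c("Q1", "Q1"))
  # remainders go to the lower quartiles
  grp9 <- group_by_quartile(dplyr::bind_rows(
    summaries, tibble::tibble(gene_id = "g09", total_enrichment = 0.5,
                              n_probes = 10L, assigned = TRUE)))
  expect_equal(as.vector(table(grp9$quartile)), c(3, 2, 2, 2))
  expect_error(group_by_quartile(summaries[1:3, ]), "at least 4")
})

test_that("group averages respect missingness and aggregate consistently", {
  vals <- matrix(c(1, NA, 3, 5), 2, 2, byrow = TRUE)
  m <- profile_matrix(vals, c("g1", "g2"), bin_layout = c(0, 1, 0))
  one <- average_profile(m, tibble::tibble(gene_id = c("g1", "g2"),
                                           group = c("a", "b")))
  expect_equal(one$mean[one$group == "a"], c(1, NA))
  expect_equal(one$n[one$group == "a"], c(1, 0))
  both <- average_profile(m)
  expect_equal(both$mean, c(2, 5))
  expect_equal(both$n, c(2, 1))

  # all-gene curve equals the coverage-weighted mean of group curves
  withr::local_seed(303)
  inst <- random_instance(12, 600)
  mm <- build_profile_matrix(assign_probes(inst$genes, inst$probes, 300), 50,
                             gene_ids = inst$genes$gene_id)
  grp <- tibble::tibble(gene_id = inst$genes$gene_id,
                        group = rep(c("u", "v", "w"), each = 4))
  per_group <- average_profile(mm, grp)
  overall <- average_profile(mm)
  agg <- per_group |>
    dplyr::filter(n > 0) |>
    dplyr::summarise(mean = sum(mean * n) / sum(n), n = sum(n), .by = bin)
  joined <- dplyr::inner_join(agg, overall, by = "bin")
  expect_equal(joined$mean.x, joined$mean.y)
  expect_equal(joined$n.x, joined$n.y)
})

test_that("mark normalization subtracts cell-wise and propagates missingness", {
  a <- profile_matrix(matrix(c(2, 1, NA, 4), 2, 2), c("g1", "g2"))
  b <- profile_matrix(matrix(c(0.5, NA, 1, 1), 2, 2), c("g1", "g2"))
  out <- normalize_to_reference(a, b)
  expect_equal(unname(pm_values(out)),
               matrix(c(1.5, NA, NA, 3), 2, 2))
  zero <- normalize_to_reference(a, a)
  expect_true(all(pm_values(zero) == 0, na.rm = TRUE))
  expect_error(normalize_to_reference(a, profile_matrix(matrix(1, 1, 2), "g1")),
               "genes")
})

test_that("noise-free simulation recovers the shape at bin centers", {
  cfg <- sim_config(n_genes = 40, noise_sd = 0, level_sd = 0, seed = 13,
                    class_levels = c(1, 1, 1, 1))
  genes <- simulate_genome(cfg)
  probes <- simulate_occupancy(genes, cfg, delta = 0.5, seed = 14)
  m <- build_profile_matrix(assign_probes(genes, probes, 300), 50,
                            gene_ids = genes$gene_id)
  avg <- average_profile(m)
  reg <- bin_regions(50, attr(m, "bin_layout"))
  centers <- (which(reg == "coding") - 0.5) / 50
  xg <- (centers - 0.1) / 0.8
  expected <- occupancy_shape(xg, 1, cfg$shape_amp5, 0.5)
  got <- avg$mean[avg$region == "coding"]
  # probes sit at midpoints, not bin centers: allow shape-slope * bin-width
  tol <- (cfg$shape_amp5 + 2 * 0.5) * (1 / (0.8 * 50))
  expect_true(all(abs(got - expected) < tol, na.rm = TRUE))
})
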