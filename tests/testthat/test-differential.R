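test_that("difference matrices subtract cell-wise over common genes", {
  a <- profile_matrix(matrix(c(2, 1, 0.5, NA), 2, 2), c("g1", "g2"))
  b <- profile_matrix(matrix(c(1, 1, 0.25, 3), 2, 2), c("g1", "g2"))
  d <- difference_matrix(a, b)
  expect_equal(unname(pm_values(d)), matrix(c(1, 0, 0.25, NA), 2, 2))
  same <- difference_matrix(a, a)
  expect_true(all(pm_values(same) == 0, na.rm = TRUE))
  c3 <- profile_matrix(matrix(1, 3, 2), c("g1", "g2", "g3"))
  expect_message(d2 <- difference_matrix(c3, a), "1 gene")
  expect_setequal(d2$gene_id, c("g1", "g2"))
  only <- profile_matrix(matrix(1, 1, 2), "gX")
  expect_error(difference_matrix(only, a), "common")
})

test_that("significance tiers honor their boundaries exactly", {
  expect_equal(classify_tier(0.5), "open")
  expect_equal(classify_tier(0.001), "light")
  expect_equal(classify_tier(1e-7), "dark")
  # boundary values fall on the significant side
  expect_equal(classify_tier(0.01), "light")
  expect_equal(classify_tier(1e-5), "dark")
  expect_equal(classify_tier(0.01 + 1e-12), "open")
  expect_equal(classify_tier(1e-5 * (1 + 1e-9)), "light")
  expect_error(classify_tier(1.2), "\\[0, 1\\]")
})

test_that("position-wise one-sample t-tests match the closed form", {
  # one group, one informative bin holding differences {1, 2, 3}
  vals <- matrix(c(1, 2, 3), 3, 1)
  d <- profile_matrix(vals, c("g1", "g2", "g3"), bin_layout = c(0, 1, 0))
  tt <- positionwise_ttest(d, min_n = 3)
  expect_equal(tt$mean_diff, 2)
  expect_equal(tt$t_stat, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(tt$n, 3)
  # closed-form two-sided p for df = 2: 1 - 2 * t / (2 * sqrt(2 + t^2))
  t0 <- 2 * sqrt(3)
  p_closed <- 1 - t0 / sqrt(2 + t0^2)
  expect_equal(tt$p_value, p_closed, tolerance = 1e-10)
  expect_equal(tt$tier, "open")
})

test_that("degenerate cells are flagged, zero-difference cells are null", {
  vals <- cbind(c(0, 0, 0), c(1, 1, 1), c(1, 2, NA))
  d <- profile_matrix(vals, paste0("g", 1:3), bin_layout = c(0, 1, 0))
  tt <- positionwise_ttest(d, min_n = 3)
  expect_equal(tt$t_stat[1], 0)
  expect_equal(tt$p_value[1], 1)
  expect_equal(tt$tier[1], "open")
  expect_false(tt$degenerate[1])
  # sd = 0 around a non-zero mean: degenerate, rendered dark, no p
  expect_true(tt$degenerate[2])
  expect_equal(tt$tier[2], "dark")
  expect_true(is.na(tt$p_value[2]))
  # n = 2 < min_n: degenerate with no statistics
  expect_true(tt$degenerate[3])
  expect_true(is.na(tt$p_value[3]))
})

test_that("tiers are monotone in |t| at fixed n", {
  withr::local_seed(7)
  n <- 8
  res <- purrr::map_dfr(seq(0.1, 6, length.out = 30), function(scale) {
    d <- scale * (1:n - mean(1:n)) / n + scale / 2
    tibble::tibble(t = mean(d) / (sd(d) / sqrt(n)),
                   p = 2 * pt(-abs(mean(d) / (sd(d) / sqrt(n))), n - 1))
  })
  res$tier <- classify_tier(res$p)
  ranks <- c(open = 1, light = 2, dark = 3)
  o <- order(abs(res$t))
  expect_true(all(diff(ranks[res$tier[o]]) >= 0))
})

test_that("difference averaging is linear when the missing masks coincide", {
  withr::local_seed(404)
  inst <- random_instance(10, 800)
  asn <- assign_probes(inst$genes, inst$probes, 300)
  m1 <- build_profile_matrix(asn, 50, gene_ids = inst$genes$gene_id)
  asn2 <- asn
  asn2$value <- asn$value * 0.5 + 0.3
  m2 <- build_profile_matrix(asn2, 50, gene_ids = inst$genes$gene_id)
  grp <- tibble::tibble(gene_id = inst$genes$gene_id,
                        group = rep(c("a", "b"), 5))
  d_avg <- average_profile(difference_matrix(m1, m2), grp)
  a_avg <- average_profile(m1, grp)
  b_avg <- average_profile(m2, grp)
  expect_equal(d_avg$mean, a_avg$mean - b_avg$mean)
})

test_that("mark correlation matches the covariance formula and edge cases", {
  mk <- function(v) tibble::tibble(gene_id = paste0("g", seq_along(v)),
                                   total_enrichment = v,
                                   n_probes = 10L, assigned = TRUE)
  a <- c(1, 2, 3)
  b <- c(1, 2, 4)
  r_hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  out <- mark_correlation(mk(a), mk(b))
  expect_equal(out$r, r_hand)
  expect_equal(out$n, 3)
  expect_equal(mark_correlation(mk(a), mk(a))$r, 1)
  expect_equal(mark_correlation(mk(a), mk(-a))$r, -1)
  expect_error(mark_correlation(mk(c(1, 1, 1)), mk(a)), "variance")
  expect_error(mark_correlation(mk(a)[1:2, ], mk(a)), "at least 3")
})

test_that("ranked changes partition by sign, order by magnitude, and flip", {
  vals <- matrix(c(2, 1, -3), 3, 1)
  d <- profile_matrix(vals, c("g1", "g2", "g3"), bin_layout = c(0, 1, 0))
  rc <- rank_changes(d, top_n = 500)
  expect_setequal(rc$gene_id[rc$direction == "increase"], c("g1", "g2"))
  expect_setequal(rc$gene_id[rc$direction == "decrease"], "g3")
  rc1 <- rank_changes(d, top_n = 1)
  expect_equal(rc1$gene_id[rc1$direction == "increase"], "g1")
  expect_equal(rc1$gene_id[rc1$direction == "decrease"], "g3")
  neg <- profile_matrix(-vals, c("g1", "g2", "g3"), bin_layout = c(0, 1, 0))
  rcn <- rank_changes(neg, top_n = 500)
  expect_equal(rcn$gene_id[rcn$direction == "increase"],
               rc$gene_id[rc$direction == "decrease"])
  expect_equal(rcn$gene_id[rcn$direction == "decrease"],
               rc$gene_id[rc$direction == "increase"])
})

test_that("change scores use coding-region bins only", {
  # 10 bins, layout (0.1, 0.8, 0.1): bin 1 and bin 10 are flanks
  vals <- matrix(c(100, rep(1, 8), -100), 1, 10)
  d <- profile_matrix(vals, "g1", bin_layout = c(0.1, 0.8, 0.1))
  rc <- rank_changes(d, top_n = 5)
  expect_equal(rc$score, 1)
  expect_equal(rc$direction, "increase")
})
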