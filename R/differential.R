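#' Per-gene condition-difference matrix
#'
#' Cell-wise `a - b` on the log2 scale over the genes common to both
#' matrices (genes present in only one are dropped with a message).
#' Cells missing in either operand are missing in the result.
#'
#' @param a,b [profile_matrix()] objects with equal bin counts.
#' @return a [profile_matrix()] of per-gene differences.
#' @export
difference_matrix <- function(a, b) {
  if (pm_n_bins(a) != pm_n_bins(b)) abort("matrices differ in bin count.")
  common <- intersect(a$gene_id, b$gene_id)
  if (length(common) == 0) abort("no genes in common between the matrices.")
  dropped <- (nrow(a) - length(common)) + (nrow(b) - length(common))
  if (dropped > 0) {
    inform(sprintf("difference_matrix: %d gene(s) present in only one condition dropped.",
                   dropped))
  }
  va <- pm_values(a)[common, , drop = FALSE]
  vb <- pm_values(b)[common, , drop = FALSE]
  profile_matrix(va - vb, common, bin_layout = attr(a, "bin_layout"))
}

#' Significance tier of a position-wise p-value
#'
#' The three-level shading convention of average-gene difference plots:
#' open symbols for p > 0.01, light shading for 1e-5 < p <= 0.01, dark
#' shading for p <= 1e-5. Boundary values are classified on the
#' significant side.
#'
#' @param p p-value(s) in `[0, 1]`.
#' @return character vector of `"open"`, `"light"`, `"dark"`.
#' @export
classify_tier <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1].")
  ifelse(p > 0.01, "open", ifelse(p > 1e-5, "light", "dark"))
}

#' Position-wise one-sample t-tests of a difference matrix
#'
#' For each occupancy group and bin, the per-gene differences present at
#' that position are tested against zero: `t = mean / (sd / sqrt(n))`
#' with the sample sd (n - 1 denominator) and a two-sided p-value from
#' the t distribution with n - 1 degrees of freedom. Cells with fewer
#' than `min_n` genes, or with zero sd around a non-zero mean, are
#' flagged degenerate and carry no p-value (zero sd with zero mean is
#' the exact null: t = 0, p = 1).
#'
#' @param diff difference [profile_matrix()] (e.g. mutant minus
#'   wild-type, from [difference_matrix()]).
#' @param groups tibble with `gene_id` and `quartile` (or `group`)
#'   column, e.g. from [group_by_quartile()] on the reference condition.
#'   Default: all genes in one group.
#' @param min_n minimum genes per (group, bin) cell.
#' @return tibble with `group`, `bin`, `region`, `mean_diff`, `t_stat`,
#'   `p_value`, `n`, `tier`, `degenerate`.
#' @export
positionwise_ttest <- function(diff, groups = NULL, min_n = 3) {
  v <- pm_values(diff)
  n_bins <- ncol(v)
  reg <- bin_regions(n_bins, attr(diff, "bin_layout"))
  if (is.null(groups)) {
    grp <- setNames(rep("all", nrow(v)), rownames(v))
  } else {
    gcol <- if ("quartile" %in% names(groups)) "quartile" else "group"
    grp <- setNames(as.character(groups[[gcol]]), groups$gene_id)[rownames(v)]
  }
  keep <- !is.na(grp)
  purrr::map_dfr(split(seq_len(nrow(v))[keep], grp[keep]), function(rows) {
    sub <- v[rows, , drop = FALSE]
    purrr::map_dfr(seq_len(n_bins), function(j) {
      d <- sub[, j]
      d <- d[!is.na(d)]
      n <- length(d)
      if (n < min_n) {
        return(tibble(bin = j, region = reg[j], mean_diff = NA_real_,
                      t_stat = NA_real_, p_value = NA_real_, n = n,
                      tier = NA_character_, degenerate = TRUE))
      }
      m <- mean(d)
      s <- sd(d)
      if (s == 0) {
        if (m == 0) {
          return(tibble(bin = j, region = reg[j], mean_diff = 0,
                        t_stat = 0, p_value = 1, n = n, tier = "open",
                        degenerate = FALSE))
        }
        return(tibble(bin = j, region = reg[j], mean_diff = m,
                      t_stat = sign(m) * Inf, p_value = NA_real_, n = n,
                      tier = "dark", degenerate = TRUE))
      }
      t <- m / (s / sqrt(n))
      p <- 2 * pt(-abs(t), df = n - 1)
      tibble(bin = j, region = reg[j], mean_diff = m, t_stat = t,
             p_value = p, n = n, tier = classify_tier(p),
             degenerate = FALSE)
    })
  }, .id = "group")
}

#' Genome-wide correlation between two marks' gene-level totals
#'
#' Pearson correlation of per-gene total enrichment over the genes
#' assignable in both conditions.
#'
#' @param summaries_a,summaries_b outputs of [gene_total_enrichment()].
#' @return one-row tibble with `r` and `n`.
#' @export
mark_correlation <- function(summaries_a, summaries_b) {
  ab <- inner_join(
    filter(summaries_a, .data$assigned),
    filter(summaries_b, .data$assigned),
    by = "gene_id", suffix = c("_a", "_b"))
  if (nrow(ab) < 3) abort("need at least 3 genes common to both marks.")
  if (sd(ab$total_enrichment_a) == 0 || sd(ab$total_enrichment_b) == 0) {
    abort("zero variance in gene-level totals; correlation undefined.")
  }
  tibble(r = cor(ab$total_enrichment_a, ab$total_enrichment_b),
         n = nrow(ab))
}

#' Rank genes by occupancy change
#'
#' The per-gene change score is the mean over non-missing coding-region
#' bins of the difference matrix. The result holds the `top_n` most
#' positive scores (`direction = "increase"`) and the `top_n` most
#' negative (`"decrease"`), each sorted by `|score|` descending with
#' ties broken by `gene_id`; lists truncate to the genes available.
#'
#' @param diff difference [profile_matrix()].
#' @param top_n list size (e.g. 500).
#' @return tibble with `gene_id`, `score`, `direction`.
#' @export
rank_changes <- function(diff, top_n = 500) {
  if (top_n < 1) abort("`top_n` must be >= 1.")
  v <- pm_values(diff)
  reg <- bin_regions(ncol(v), attr(diff, "bin_layout"))
  cv <- v[, reg == "coding", drop = FALSE]
  score <- rowMeans(cv, na.rm = TRUE)
  ok <- !is.nan(score)
  scores <- tibble(gene_id = rownames(v)[ok], score = unname(score[ok]))
  pick <- function(s, dir) {
    s |>
      arrange(dplyr::desc(abs(.data$score)), .data$gene_id) |>
      head(top_n) |>
      mutate(direction = dir)
  }
  bind_rows(pick(filter(scores, .data$score > 0), "increase"),
            pick(filter(scores, .data$score < 0), "decrease"))
}
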