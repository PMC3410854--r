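#' Percent input of ChIP-qPCR measurements
#'
#' Adds a `percent_input` column: `100 * ip_signal / (input_signal /
#' input_fraction)`. Dividing the input signal by the aliquot fraction
#' converts it to the signal the whole chromatin input would have given,
#' so the result is the percentage of input chromatin recovered by the
#' IP at that primer pair. Invariant under common rescaling of the two
#' signals.
#'
#' @param data tibble with `ip_signal`, `input_signal` and optionally
#'   `input_fraction` (default 1).
#' @return `data` with a `percent_input` column appended.
#' @export
percent_input <- function(data) {
  if (!"input_fraction" %in% names(data)) data$input_fraction <- 1
  if (any(data$input_signal <= 0)) {
    abort("input_signal must be > 0 to express enrichment as percent input.")
  }
  if (any(data$input_fraction <= 0 | data$input_fraction > 1)) {
    abort("input_fraction must lie in (0, 1].")
  }
  mutate(data, percent_input =
           100 * .data$ip_signal / (.data$input_signal / .data$input_fraction))
}

#' Replicate-wise ratio of two percent-input tables
#'
#' Joins numerator and denominator on target and replicate and forms the
#' per-replicate ratio (e.g. phospho-epitope over total-protein
#' occupancy). Ratios are taken per replicate and meant to be averaged
#' afterwards with [replicate_stats()] — not as a ratio of means, so the
#' per-experiment error structure survives. Zero denominators flag the
#' ratio undefined (`NA`) for that replicate with a warning; other
#' targets are unaffected.
#'
#' @param numerator,denominator tibbles carrying `target`, `replicate`
#'   and `percent_input` (see [percent_input()]).
#' @return tibble with `target`, `replicate`, `ratio`.
#' @export
normalize_ratio <- function(numerator, denominator) {
  ab <- inner_join(numerator[, c("target", "replicate", "percent_input")],
                   denominator[, c("target", "replicate", "percent_input")],
                   by = c("target", "replicate"),
                   suffix = c("_num", "_den"))
  zero <- ab$percent_input_den == 0
  if (any(zero)) {
    warn(sprintf("normalize_ratio: %d replicate(s) with zero denominator flagged undefined (%s).",
                 sum(zero), paste(unique(ab$target[zero]), collapse = ", ")))
  }
  tibble(target = ab$target, replicate = ab$replicate,
         ratio = ifelse(zero, NA_real_,
                        ab$percent_input_num / ab$percent_input_den))
}

#' Replicate summary: mean, sd, n
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) per
#' group — the numbers behind bar-plus-error-bar qPCR panels. The sd is
#' `NA` for a single replicate.
#'
#' @param data replicate-level tibble.
#' @param value name of the value column (default `percent_input`, use
#'   `"ratio"` for [normalize_ratio()] output).
#' @param by grouping columns.
#' @return tibble with the grouping columns plus `mean`, `sd`, `n`.
#' @export
replicate_stats <- function(data, value = "percent_input",
                            by = intersect(c("target", "condition"),
                                           names(data))) {
  if (nrow(data) == 0) abort("no replicates to summarise.")
  v <- data[[value]]
  if (is.null(v)) abort(sprintf("column `%s` not found.", value))
  data |>
    summarise(mean = mean(.data[[value]]),
              sd = if (dplyr::n() > 1) sd(.data[[value]]) else NA_real_,
              n = dplyr::n(),
              .by = dplyr::all_of(by))
}

#' Welch unpaired t-test with qPCR significance stars
#'
#' Two-sample two-sided t-test with Welch (unequal-variance) degrees of
#' freedom, as used to compare wild-type and mutant replicate
#' enrichments. Stars follow the convention `"*"` for p < 0.04 and
#' `"**"` for p < 0.02. Degenerate inputs (a group with fewer than two
#' replicates, or zero variance in both groups with equal means) return
#' `p = 1` and no stars rather than an error.
#'
#' @param a,b numeric replicate vectors for the two conditions.
#' @return one-row tibble with `t_stat`, `df`, `p_value`, `stars`.
#' @export
unpaired_ttest <- function(a, b) {
  degenerate <- function() tibble(t_stat = 0, df = NA_real_, p_value = 1,
                                  stars = "")
  if (length(a) < 2 || length(b) < 2) {
    warn("unpaired_ttest: a group has fewer than 2 replicates; returning p = 1.")
    return(degenerate())
  }
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) return(degenerate())
    return(tibble(t_stat = sign(mean(a) - mean(b)) * Inf, df = NA_real_,
                  p_value = 0, stars = "**"))
  }
  tt <- t.test(a, b, var.equal = FALSE)
  p <- tt$p.value
  tibble(t_stat = unname(tt$statistic), df = unname(tt$parameter),
         p_value = p, stars = significance_stars(p))
}

#' @rdname unpaired_ttest
#' @param p p-value(s).
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.02, "**", ifelse(p < 0.04, "*", ""))
}

#' Summarise a full qPCR table against a reference condition
#'
#' Convenience wrapper over [percent_input()], [replicate_stats()] and
#' [unpaired_ttest()]: computes percent input per replicate, summarises
#' each target x condition, and tests every non-reference condition
#' against the reference per target.
#'
#' @param data replicate table (see [read_qpcr()]).
#' @param reference condition label to test against.
#' @return list with `summary` (mean/sd/n per target x condition) and
#'   `tests` (per target x condition t-test vs the reference).
#' @export
qpcr_analysis <- function(data, reference = "wt") {
  if (!reference %in% data$condition) {
    abort(sprintf("reference condition '%s' not present in table.", reference))
  }
  pi_tbl <- percent_input(data)
  summary <- replicate_stats(pi_tbl)
  others <- setdiff(unique(pi_tbl$condition), reference)
  tests <- purrr::map_dfr(others, function(cond) {
    purrr::map_dfr(unique(pi_tbl$target), function(tg) {
      a <- pi_tbl$percent_input[pi_tbl$target == tg & pi_tbl$condition == cond]
      b <- pi_tbl$percent_input[pi_tbl$target == tg &
                                  pi_tbl$condition == reference]
      bind_cols(tibble(target = tg, condition = cond), unpaired_ttest(a, b))
    })
  })
  list(summary = summary, tests = tests)
}
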