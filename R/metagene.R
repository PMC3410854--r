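#' Map probes into scaled average-gene coordinates
#'
#' Each probe is assigned to the gene whose flank-extended span
#' `[start - flank_bp, end + flank_bp)` contains its midpoint. If the
#' midpoint falls in two extended spans it goes to the gene whose coding
#' region is nearer (exact ties are dropped). The scaled coordinate `x`
#' runs 5' to 3' in `[0, 1]` (minus-strand genes are flipped) and is
#' piecewise linear: the 5' flank maps onto the first `bin_layout[1]`
#' fraction of `x`, the coding region onto the middle `bin_layout[2]`,
#' the 3' flank onto the rest. With `flank_bp = 0` the layout collapses
#' to `(0, 1, 0)` and `x` spans the coding region alone.
#'
#' @param genes gene tibble (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`), 0-based half-open.
#' @param probes probe tibble (`chrom`, `start`, `end`, `value`).
#' @param flank_bp flank extension in bp (>= 0).
#' @param bin_layout length-3 fractions `(flank5, coding, flank3)`.
#' @return tibble with `gene_id`, `x`, `value`; attribute `bin_layout`
#'   records the layout actually used.
#' @export
assign_probes <- function(genes, probes, flank_bp = 300,
                          bin_layout = c(0.1, 0.8, 0.1)) {
  if (flank_bp < 0) abort("`flank_bp` must be >= 0.")
  check_bin_layout(bin_layout)
  if (flank_bp == 0) bin_layout <- c(0, 1, 0)
  mid <- (probes$start + probes$end) / 2
  hit <- match_probe_gene(probes$chrom, mid, genes, flank_bp)
  keep <- !is.na(hit$gene)
  g <- hit$gene[keep]
  m <- mid[keep]
  gs <- genes$start[g]; ge <- genes$end[g]
  minus <- genes$strand[g] == "-"
  # genomic left-to-right fractions; strand flip swaps the flank shares
  fL <- ifelse(minus, bin_layout[3], bin_layout[1])
  fC <- bin_layout[2]
  x <- numeric(length(m))
  left <- m < gs
  right <- m >= ge
  mid_reg <- !left & !right
  if (flank_bp > 0) {
    x[left] <- fL[left] * (m[left] - (gs[left] - flank_bp)) / flank_bp
    x[right] <- (fL[right] + fC) +
      (1 - fL[right] - fC) * (m[right] - ge[right]) / flank_bp
  }
  x[mid_reg] <- fL[mid_reg] +
    fC * (m[mid_reg] - gs[mid_reg]) / (ge[mid_reg] - gs[mid_reg])
  x <- ifelse(minus, 1 - x, x)
  out <- tibble(gene_id = genes$gene_id[g], x = x,
                value = probes$value[keep])
  attr(out, "bin_layout") <- bin_layout
  out
}

#' Bin scaled-position assignments into a profile matrix
#'
#' Bin `j` of `n_bins` covers `x` in `[(j-1)/n, j/n)`, with the last bin
#' closed at 1. Each cell is the arithmetic mean of the probe values
#' assigned to that gene and bin; cells without probes are missing.
#'
#' @param assignments output of [assign_probes()].
#' @param n_bins number of positions along the average gene.
#' @param gene_ids genes to include as rows (default: genes present in
#'   `assignments`); genes without any probe get an all-missing row.
#' @param bin_layout layout to stamp on the result (default: taken from
#'   `assignments`).
#' @return a [profile_matrix()].
#' @export
build_profile_matrix <- function(assignments, n_bins = 50, gene_ids = NULL,
                                 bin_layout = NULL) {
  if (n_bins < 1) abort("`n_bins` must be >= 1.")
  bin_layout <- bin_layout %||% attr(assignments, "bin_layout") %||%
    c(0.1, 0.8, 0.1)
  gene_ids <- gene_ids %||% unique(assignments$gene_id)
  # findInterval reproduces the bin contract exactly: bin j is
  # [ (j-1)/n, j/n ), with the last bin closed at 1
  bin <- findInterval(assignments$x, (0:n_bins) / n_bins,
                      rightmost.closed = TRUE)
  cells <- tibble(gene_id = assignments$gene_id, bin = bin,
                  value = assignments$value) |>
    summarise(value = mean(.data$value), .by = c("gene_id", "bin"))
  vals <- matrix(NA_real_, nrow = length(gene_ids), ncol = n_bins)
  ri <- match(cells$gene_id, gene_ids)
  ok <- !is.na(ri)
  vals[cbind(ri[ok], cells$bin[ok])] <- cells$value[ok]
  profile_matrix(vals, gene_ids, bin_layout = bin_layout)
}

#' Per-gene total enrichment over the coding region
#'
#' The total is the mean value of probes whose midpoint lies in the
#' coding region `[start, end)` — flanks never contribute. Genes with
#' fewer than `min_probes` coding probes are flagged unassigned and are
#' excluded from quartile grouping and downstream statistics.
#'
#' @inheritParams assign_probes
#' @param min_probes minimum coding-region probe count for a gene to be
#'   assignable.
#' @return tibble with `gene_id`, `total_enrichment`, `n_probes`,
#'   `assigned`.
#' @export
gene_total_enrichment <- function(genes, probes, min_probes = 5) {
  asn <- assign_probes(genes, probes, flank_bp = 0)
  stats <- asn |>
    summarise(total_enrichment = mean(.data$value),
              n_probes = dplyr::n(), .by = "gene_id")
  genes |>
    select("gene_id") |>
    left_join(stats, by = "gene_id") |>
    mutate(n_probes = dplyr::coalesce(.data$n_probes, 0L),
           assigned = .data$n_probes >= min_probes)
}

#' Group genes into occupancy quartiles of a reference condition
#'
#' Genes are ranked by the *reference* condition's total enrichment and
#' split into `n_groups` equal-size classes — Q1 lowest to Q4 highest
#' occupancy. Remainders go to the lower quartiles; ties are broken by
#' `gene_id`. Labels are then attached to `summaries` regardless of that
#' condition's own values, so a mutant can be stratified by wild-type
#' occupancy.
#'
#' @param summaries gene summaries ([gene_total_enrichment()]) to label.
#' @param reference gene summaries supplying the ranking (default:
#'   `summaries` itself).
#' @param n_groups number of classes (default 4, quartiles).
#' @return `summaries` with a `quartile` factor column (`Q1`..`Qn`; `NA`
#'   for genes unassignable in the reference).
#' @export
group_by_quartile <- function(summaries, reference = summaries,
                              n_groups = 4) {
  if (!all(summaries$gene_id %in% reference$gene_id)) {
    abort("`reference` must cover every gene in `summaries`.")
  }
  ref <- reference |>
    filter(.data$assigned) |>
    arrange(.data$total_enrichment, .data$gene_id)
  n <- nrow(ref)
  if (n < n_groups) {
    abort(sprintf("need at least %d assignable genes to form %d groups.",
                  n_groups, n_groups))
  }
  base <- n %/% n_groups
  extra <- n %% n_groups
  sizes <- base + (seq_len(n_groups) <= extra)
  labels <- factor(paste0("Q", seq_len(n_groups)),
                   levels = paste0("Q", seq_len(n_groups)))
  ref$quartile <- rep(labels, times = sizes)
  summaries |>
    left_join(ref[, c("gene_id", "quartile")], by = "gene_id")
}

#' Group-average metagene curves
#'
#' For each group and bin, the mean over genes with a non-missing cell;
#' the contributing gene count `n` is reported and empty cells stay
#' missing.
#'
#' @param m a [profile_matrix()].
#' @param groups optional tibble with `gene_id` and a `quartile` (or
#'   `group`) column; genes with `NA` group are dropped. Default: one
#'   group `"all"`.
#' @return tibble with `group`, `bin`, `region`, `mean`, `n`.
#' @export
average_profile <- function(m, groups = NULL) {
  v <- pm_values(m)
  n_bins <- ncol(v)
  reg <- bin_regions(n_bins, attr(m, "bin_layout"))
  if (is.null(groups)) {
    grp <- setNames(rep("all", nrow(v)), rownames(v))
  } else {
    gcol <- if ("quartile" %in% names(groups)) "quartile" else "group"
    grp <- setNames(as.character(groups[[gcol]]), groups$gene_id)[rownames(v)]
  }
  keep <- !is.na(grp)
  purrr::map_dfr(split(seq_len(nrow(v))[keep], grp[keep]), function(rows) {
    sub <- v[rows, , drop = FALSE]
    tibble(bin = seq_len(n_bins), region = reg,
           mean = unname(colMeans(sub, na.rm = TRUE)),
           n = unname(colSums(!is.na(sub))))
  }, .id = "group") |>
    mutate(mean = ifelse(.data$n == 0, NA_real_, .data$mean))
}

#' Normalize a mark's profile matrix to a reference mark
#'
#' Cell-wise subtraction on the log2 scale (e.g. ubiquitylated H2B minus
#' total H2B, yielding per-nucleosome modification density). Cells
#' missing in either operand are missing in the result.
#'
#' @param mark,reference [profile_matrix()] objects with identical genes
#'   and bins.
#' @return a [profile_matrix()] of `mark - reference`.
#' @export
normalize_to_reference <- function(mark, reference) {
  if (pm_n_bins(mark) != pm_n_bins(reference)) {
    abort("matrices differ in bin count.")
  }
  if (!setequal(mark$gene_id, reference$gene_id)) {
    abort("matrices must cover the same genes.")
  }
  vm <- pm_values(mark)
  vr <- pm_values(reference)[mark$gene_id, , drop = FALSE]
  profile_matrix(vm - vr, mark$gene_id,
                 bin_layout = attr(mark, "bin_layout"))
}
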