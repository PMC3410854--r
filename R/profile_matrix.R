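#' Profile matrices: genes x scaled-gene positions
#'
#' A `profile_matrix` is a tibble with a `gene_id` column followed by one
#' numeric column per position bin along the scaled "average gene"
#' (`p01`, `p02`, ...). `NA` cells mean "no probe fell in that bin for that
#' gene". Two attributes travel with the object: `n_bins` and `bin_layout`,
#' the fractions of bins covering the 5' flank, the coding region and the
#' 3' flank (they sum to 1).
#'
#' @param values numeric matrix, genes in rows, bins in columns.
#' @param gene_ids character vector, one id per row of `values`.
#' @param bin_layout numeric length-3 vector `(flank5, coding, flank3)`.
#' @return a `profile_matrix` tibble.
#' @export
profile_matrix <- function(values, gene_ids, bin_layout = c(0.1, 0.8, 0.1)) {
  values <- as.matrix(values)
  if (length(gene_ids) != nrow(values)) {
    abort("`gene_ids` must have one entry per row of `values`.")
  }
  if (anyDuplicated(gene_ids)) abort("duplicate gene_id in profile matrix.")
  check_bin_layout(bin_layout)
  n_bins <- ncol(values)
  if (n_bins < 1) abort("a profile matrix needs at least one bin.")
  if (any(is.infinite(values))) abort("profile values must be finite or NA.")
  out <- tibble(gene_id = as.character(gene_ids))
  cols <- as_tibble(values, .name_repair = "minimal")
  names(cols) <- bin_labels(n_bins)
  out <- bind_cols(out, cols)
  new_profile_matrix(out, bin_layout)
}

new_profile_matrix <- function(df, bin_layout) {
  structure(df,
    bin_layout = as.numeric(bin_layout),
    class = c("profile_matrix", class(tibble())))
}

bin_labels <- function(n_bins) sprintf("p%02d", seq_len(n_bins))

check_bin_layout <- function(bin_layout) {
  if (length(bin_layout) != 3 || any(bin_layout < 0) ||
      abs(sum(bin_layout) - 1) > 1e-8) {
    abort("`bin_layout` must be three non-negative fractions summing to 1.")
  }
  invisible(bin_layout)
}

#' @export
print.profile_matrix <- function(x, ...) {
  lay <- attr(x, "bin_layout")
  cat(sprintf("# profile_matrix: %d genes x %d bins (layout %s)\n",
              nrow(x), pm_n_bins(x), paste(format(lay), collapse = "/")))
  NextMethod()
}

#' Number of bins of a profile matrix
#' @param m a `profile_matrix`.
#' @return integer bin count.
#' @export
pm_n_bins <- function(m) ncol(m) - 1L

#' Extract the numeric cell matrix of a profile matrix
#' @param m a `profile_matrix`.
#' @return numeric matrix with gene_id rownames; `NA` marks missing cells.
#' @export
pm_values <- function(m) {
  v <- as.matrix(m[, -1, drop = FALSE])
  storage.mode(v) <- "double"
  rownames(v) <- m$gene_id
  v
}

#' Bin region labels implied by a bin layout
#'
#' Splits the bins of a profile matrix into 5' flank, coding and 3' flank
#' segments. Bin counts are `round(fraction * n_bins)` for the flanks with
#' the coding region taking the rest, so the default layout
#' `(0.1, 0.8, 0.1)` at 50 bins gives 5 + 40 + 5.
#'
#' @param n_bins integer number of bins.
#' @param bin_layout length-3 fractions `(flank5, coding, flank3)`.
#' @return character vector of length `n_bins` with values
#'   `"flank5"`, `"coding"`, `"flank3"`.
#' @export
bin_regions <- function(n_bins, bin_layout = c(0.1, 0.8, 0.1)) {
  check_bin_layout(bin_layout)
  k5 <- round(bin_layout[1] * n_bins)
  k3 <- round(bin_layout[3] * n_bins)
  kc <- n_bins - k5 - k3
  if (kc < 1) abort("bin layout leaves no coding bins.")
  rep(c("flank5", "coding", "flank3"), times = c(k5, kc, k3))
}

# Gene-body scaled coordinate of each bin center; NA for flank bins.
bin_gene_x <- function(n_bins, bin_layout) {
  reg <- bin_regions(n_bins, bin_layout)
  centers <- (seq_len(n_bins) - 0.5) / n_bins
  f5 <- sum(reg == "flank5") / n_bins
  fc <- sum(reg == "coding") / n_bins
  x <- (centers - f5) / fc
  x[reg != "coding"] <- NA_real_
  x
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a profile matrix into long (gene, bin, value) form
#'
#' @param x a `profile_matrix`.
#' @param ... unused.
#' @return tibble with `gene_id`, `bin` (integer), `region`, `value`;
#'   missing cells are dropped.
#' @method tidy profile_matrix
#' @export
tidy.profile_matrix <- function(x, ...) {
  reg <- bin_regions(pm_n_bins(x), attr(x, "bin_layout"))
  as_tibble(x) |>
    tidyr::pivot_longer(-"gene_id", names_to = "bin", values_to = "value") |>
    mutate(bin = match(.data$bin, bin_labels(pm_n_bins(x))),
           region = reg[.data$bin]) |>
    filter(!is.na(.data$value)) |>
    select("gene_id", "bin", "region", "value")
}

#' One-row summary of a profile matrix
#'
#' @param x a `profile_matrix`.
#' @param ... unused.
#' @return tibble with gene/bin counts and the fraction of missing cells.
#' @method glance profile_matrix
#' @export
glance.profile_matrix <- function(x, ...) {
  v <- pm_values(x)
  tibble(n_genes = nrow(v), n_bins = ncol(v),
         prop_missing = mean(is.na(v)),
         mean_value = mean(v, na.rm = TRUE))
}
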