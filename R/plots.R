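#' Plot group-average metagene curves
#'
#' Average-gene occupancy curves, one line per group, with the coding
#' region marked by a grey band along the x axis.
#'
#' @param avg tibble from [average_profile()].
#' @return a ggplot object.
#' @export
plot_average_profile <- function(avg) {
  n_bins <- max(avg$bin)
  coding <- range(avg$bin[avg$region == "coding"])
  ggplot2::ggplot(avg, ggplot2::aes(x = .data$bin, y = .data$mean,
                                    colour = .data$group)) +
    ggplot2::annotate("rect", xmin = coding[1] - 0.5, xmax = coding[2] + 0.5,
                      ymin = -Inf, ymax = Inf, alpha = 0.08) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = sprintf("position along the average gene (1..%d)", n_bins),
                  y = "mean log2 enrichment", colour = "group") +
    ggplot2::theme_minimal()
}

#' Plot a difference profile with significance-tier shading
#'
#' Mutant-minus-wild-type average difference per group, with each point
#' drawn per the three-tier convention: open symbols (p > 0.01), light
#' fill (1e-5 < p <= 0.01), dark fill (p <= 1e-5).
#'
#' @param diff_profile tibble from [positionwise_ttest()].
#' @return a ggplot object.
#' @export
plot_difference_profile <- function(diff_profile) {
  dp <- filter(diff_profile, !.data$degenerate)
  dp$tier <- factor(dp$tier, levels = c("open", "light", "dark"))
  ggplot2::ggplot(dp, ggplot2::aes(x = .data$bin, y = .data$mean_diff,
                                   group = .data$group)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line(ggplot2::aes(colour = .data$group)) +
    ggplot2::geom_point(ggplot2::aes(fill = .data$tier,
                                     colour = .data$group),
                        shape = 22, size = 1.8) +
    ggplot2::scale_fill_manual(
      values = c(open = "white", light = "grey70", dark = "grey20"),
      drop = FALSE) +
    ggplot2::labs(x = "position along the average gene",
                  y = "mean difference (log2)", fill = "significance") +
    ggplot2::theme_minimal()
}

#' Autoplot a profile matrix
#'
#' Heat-style overview of a profile matrix: genes in rows, bins in
#' columns, missing cells blank.
#'
#' @param object a [profile_matrix()].
#' @param ... unused.
#' @return a ggplot object.
#' @importFrom ggplot2 autoplot
#' @method autoplot profile_matrix
#' @export
autoplot.profile_matrix <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$bin, y = .data$gene_id,
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "bin", y = NULL, fill = "log2") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' @export
ggplot2::autoplot
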