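#' End-to-end analysis pipeline on synthetic or supplied data
#'
#' Runs simulate -> profile -> quartiles -> difference/t-test ->
#' correlation -> ranked changes -> category enrichment with one
#' configuration, writing every table as plain TSV plus a JSON manifest.
#' Given the same configuration and seed the output files are
#' byte-identical. Inputs referenced by path are validated before any
#' computation; if a stage fails, a `FAILED` marker file holding the
#' error message is left in the output directory.
#'
#' @param config either a list or a YAML file path. Recognised entries
#'   (all optional): `seed`; `sim` (arguments to [sim_config()]);
#'   `mutant` (list with `delta`, `amp5` overriding the mutant
#'   condition's effect sizes); `flank_bp`, `n_bins`, `bin_layout`,
#'   `min_probes`, `min_n`, `top_n`; `probes_wt`, `probes_mut`, `genes`
#'   (paths to existing BED files, replacing simulation); `categories`
#'   (path to a TSV category map, otherwise simulated).
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory results (`genes`,
#'   `groups`, `diff_profile`, `correlation`, `changes`, `enrichment`,
#'   `manifest`).
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  paths <- config[intersect(c("probes_wt", "probes_mut", "genes",
                              "categories"), names(config))]
  missing <- paths[!vapply(paths, file.exists, logical(1))]
  if (length(missing)) {
    abort(sprintf("input file(s) not found: %s",
                  paste(unlist(missing), collapse = ", ")))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  marker <- file.path(out_dir, "FAILED")
  if (file.exists(marker)) unlink(marker)
  tryCatch(
    run_pipeline_impl(config, out_dir),
    error = function(e) {
      writeLines(conditionMessage(e), marker)
      abort(sprintf("pipeline failed (marker written to %s): %s",
                    marker, conditionMessage(e)))
    })
}

run_pipeline_impl <- function(config, out_dir) {
  seed <- config$seed %||% 1L
  scfg <- do.call(sim_config, c(config$sim %||% list(),
                                if (is.null(config$sim$seed)) list(seed = seed)))
  flank_bp <- config$flank_bp %||% 300
  n_bins <- config$n_bins %||% 50
  bin_layout <- config$bin_layout %||% c(0.1, 0.8, 0.1)
  min_probes <- config$min_probes %||% 5
  min_n <- config$min_n %||% 3
  top_n <- config$top_n %||% 500
  mut <- config$mutant %||% list()
  mut_delta <- mut$delta %||% scfg$shift_delta
  mut_amp5 <- mut$amp5 %||% (scfg$shape_amp5 / 2)

  out <- function(name) file.path(out_dir, name)

  if (!is.null(config$genes)) {
    genes <- read_gene_annotation(config$genes,
                                  dialect = config$dialect %||% "bed6")
    probes_wt <- read_probe_bed(config$probes_wt)
    probes_mut <- read_probe_bed(config$probes_mut)
    probes_mark <- NULL
  } else {
    genes <- simulate_genome(scfg)
    probes_wt <- simulate_occupancy(genes, scfg, delta = 0,
                                    seed = scfg$seed + 1L)
    probes_mut <- simulate_occupancy(genes, scfg, delta = mut_delta,
                                     amp5 = mut_amp5, seed = scfg$seed + 2L)
    probes_mark <- simulate_correlated_mark(genes, scfg,
                                            seed = scfg$seed + 3L)
    write_gene_bed6(genes, out("genes.bed"))
    write_probe_bed(probes_wt, out("probes_wt.bed"))
    write_probe_bed(probes_mut, out("probes_mut.bed"))
    write_probe_bed(probes_mark, out("probes_mark.bed"))
  }

  asn_wt <- assign_probes(genes, probes_wt, flank_bp, bin_layout)
  asn_mut <- assign_probes(genes, probes_mut, flank_bp, bin_layout)
  mat_wt <- build_profile_matrix(asn_wt, n_bins, gene_ids = genes$gene_id)
  mat_mut <- build_profile_matrix(asn_mut, n_bins, gene_ids = genes$gene_id)
  write_profile_matrix(mat_wt, out("matrix_wt.tsv"))
  write_profile_matrix(mat_mut, out("matrix_mut.tsv"))

  tot_wt <- gene_total_enrichment(genes, probes_wt, min_probes)
  tot_mut <- gene_total_enrichment(genes, probes_mut, min_probes)
  groups <- group_by_quartile(tot_wt)
  readr::write_tsv(groups, out("groups.tsv"))

  diff <- difference_matrix(mat_mut, mat_wt)
  diff_profile <- positionwise_ttest(diff, groups, min_n = min_n)
  readr::write_tsv(diff_profile, out("diffprofile.tsv"))

  correlation <- NULL
  if (!is.null(probes_mark)) {
    tot_mark <- gene_total_enrichment(genes, probes_mark, min_probes)
    correlation <- mark_correlation(tot_wt, tot_mark)
    readr::write_tsv(correlation, out("correlation.tsv"))
  }

  changes <- rank_changes(diff, top_n)
  readr::write_tsv(changes, out("rank_changes.tsv"))

  categories <- if (!is.null(config$categories)) {
    read_categories(config$categories)
  } else {
    cats <- simulate_categories(genes, seed = scfg$seed + 4L)
    readr::write_tsv(cats, out("categories.tsv"))
    cats
  }
  universe <- tot_wt$gene_id[tot_wt$assigned]
  decreased <- intersect(changes$gene_id[changes$direction == "decrease"],
                         universe)
  enrichment <- category_enrichment(decreased, categories, universe)
  readr::write_tsv(enrichment, out("enrich.tsv"))

  n_retained <- sum(tot_wt$assigned)
  files <- setdiff(list.files(out_dir), c("manifest.json", "FAILED"))
  manifest <- list(
    package = "metachip",
    version = as.character(utils::packageVersion("metachip")),
    seed = seed,
    parameters = list(flank_bp = flank_bp, n_bins = n_bins,
                      bin_layout = bin_layout, min_probes = min_probes,
                      min_n = min_n, top_n = top_n,
                      mutant = list(delta = mut_delta, amp5 = mut_amp5),
                      sim = unclass(scfg)),
    gene_counts = list(total = nrow(genes), assignable = n_retained,
                       per_quartile = as.list(table(groups$quartile))),
    checksums = as.list(tools::md5sum(file.path(out_dir, sort(files))) |>
                          setNames(sort(files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  inform(sprintf("pipeline: %d/%d genes assignable; outputs in %s",
                 n_retained, nrow(genes), out_dir))
  invisible(list(genes = genes, groups = groups,
                 diff_profile = diff_profile, correlation = correlation,
                 changes = changes, enrichment = enrichment,
                 manifest = manifest))
}
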