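#' Read a probe-level enrichment BED track
#'
#' Tiling-array ChIP enrichment is distributed as BED-like value tracks:
#' tab-separated `chrom start end value` lines where `value` is the
#' normalized log2(IP/reference) ratio of one probe. Coordinates are
#' 0-based half-open. `track`/`browser` lines, `#` comments and blank
#' lines are skipped; everything else must parse, and malformed lines are
#' reported with their file line number.
#'
#' @param path path to the BED file.
#' @param score_col 1-based column holding the enrichment value. The
#'   default (4) reads plain 4-column value tracks; feature BEDs with a
#'   name in column 4 can use `score_col = 5`.
#' @param min_fields minimum number of tab-separated fields a data line
#'   must have (at least `score_col`).
#' @return tibble with `chrom`, `start`, `end`, `value`, in file order.
#' @export
read_probe_bed <- function(path, score_col = 4, min_fields = score_col) {
  if (!file.exists(path)) abort(sprintf("probe BED not found: %s", path))
  if (score_col < 4) abort("`score_col` must be >= 4.")
  min_fields <- max(min_fields, score_col)
  lines <- readr::read_lines(path)
  skip <- grepl("^(track|browser)\\b|^#", lines) | !nzchar(trimws(lines))
  keep <- which(!skip)
  if (length(keep) == 0) {
    return(tibble(chrom = character(), start = integer(),
                  end = integer(), value = double()))
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad_line <- function(i, why) {
    abort(sprintf("%s: line %d: %s", path, keep[i], why))
  }
  if (any(nf < min_fields)) {
    i <- which(nf < min_fields)[1]
    bad_line(i, sprintf("expected >= %d tab-separated fields, found %d",
                        min_fields, nf[i]))
  }
  pick <- function(j) vapply(fields, `[[`, character(1), j)
  start <- suppressWarnings(as.numeric(pick(2)))
  end <- suppressWarnings(as.numeric(pick(3)))
  value <- suppressWarnings(as.numeric(pick(score_col)))
  for (chk in list(list(start, "start"), list(end, "end"))) {
    if (anyNA(chk[[1]])) bad_line(which(is.na(chk[[1]]))[1],
                                  sprintf("non-numeric %s", chk[[2]]))
  }
  if (anyNA(value)) bad_line(which(is.na(value))[1], "non-numeric score")
  if (any(!is.finite(value))) bad_line(which(!is.finite(value))[1],
                                       "non-finite score")
  if (any(start < 0)) bad_line(which(start < 0)[1], "negative start")
  if (any(end <= start)) bad_line(which(end <= start)[1], "end <= start")
  tibble(chrom = pick(1), start = as.integer(start),
         end = as.integer(end), value = value)
}

#' Write a probe tibble as a 4-column BED value track
#'
#' Values are written with readr's shortest round-trippable formatting, so
#' `read_probe_bed(write_probe_bed(x))` reproduces `x` exactly.
#'
#' @param probes tibble with `chrom`, `start`, `end`, `value`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_probe_bed <- function(probes, path) {
  readr::write_tsv(probes[, c("chrom", "start", "end", "value")], path,
                   col_names = FALSE)
  invisible(path)
}

#' Read gene models from BED6 or GFF3
#'
#' Returns genes in the package-wide convention: 0-based half-open
#' coordinates with `+`/`-` strands. GFF3 (1-based closed) is converted on
#' read; for GFF3 files only records of type `gene` are used when present,
#' otherwise all records. Duplicate gene ids are an error.
#'
#' @param path annotation file.
#' @param dialect `"bed6"` or `"gff3"`.
#' @return tibble with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_gene_annotation <- function(path, dialect = c("bed6", "gff3")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("annotation not found: %s", path))
  if (dialect == "bed6") {
    genes <- read_genes_bed6(path)
  } else {
    gr <- rtracklayer::import(path, format = "gff3")
    if ("type" %in% names(S4Vectors::mcols(gr)) &&
        any(S4Vectors::mcols(gr)$type == "gene")) {
      gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
    }
    mc <- S4Vectors::mcols(gr)
    ids <- if ("ID" %in% names(mc) && !all(is.na(mc$ID))) mc$ID else mc$Name
    if (is.null(ids) || anyNA(ids)) {
      abort(sprintf("%s: GFF3 gene records need an ID or Name attribute", path))
    }
    genes <- tibble(
      gene_id = as.character(ids),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)))
  }
  if (any(!genes$strand %in% c("+", "-"))) {
    bad <- genes$strand[!genes$strand %in% c("+", "-")][1]
    abort(sprintf("%s: unknown strand character '%s'", path, bad))
  }
  if (anyDuplicated(genes$gene_id)) {
    dup <- genes$gene_id[duplicated(genes$gene_id)][1]
    abort(sprintf("%s: duplicate gene_id '%s'", path, dup))
  }
  if (any(genes$start >= genes$end)) abort(sprintf("%s: gene with start >= end", path))
  genes
}

read_genes_bed6 <- function(path) {
  lines <- readr::read_lines(path)
  keep <- which(!(grepl("^(track|browser)\\b|^#", lines) | !nzchar(trimws(lines))))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  if (length(keep) && any(lengths(fields) < 6)) {
    i <- which(lengths(fields) < 6)[1]
    abort(sprintf("%s: line %d: BED6 needs 6 fields", path, keep[i]))
  }
  pick <- function(j) vapply(fields, `[[`, character(1), j)
  if (length(keep) == 0) {
    return(tibble(gene_id = character(), chrom = character(),
                  start = integer(), end = integer(), strand = character()))
  }
  start <- suppressWarnings(as.integer(pick(2)))
  end <- suppressWarnings(as.integer(pick(3)))
  if (anyNA(start) || anyNA(end)) {
    abort(sprintf("%s: non-numeric coordinates", path))
  }
  tibble(gene_id = pick(4), chrom = pick(1), start = start, end = end,
         strand = pick(6))
}

#' Write a gene tibble as BED6
#' @param genes tibble with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_bed6 <- function(genes, path) {
  out <- tibble(chrom = genes$chrom, start = genes$start, end = genes$end,
                name = genes$gene_id, score = ".", strand = genes$strand)
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Serialize / deserialize a profile matrix as TSV
#'
#' The format is plain tab-separated text: one comment line recording the
#' bin layout, a header of `gene_id` plus bin labels, and one row per gene
#' with missing cells written as `NA`. `read_profile_matrix()` inverts
#' `write_profile_matrix()` exactly (values and missing mask).
#'
#' @param m a `profile_matrix`.
#' @param path file path.
#' @return `write_profile_matrix()` returns `path` invisibly;
#'   `read_profile_matrix()` returns a `profile_matrix`.
#' @export
write_profile_matrix <- function(m, path) {
  stopifnot(inherits(m, "profile_matrix"))
  lay <- attr(m, "bin_layout")
  writeLines(sprintf("# bin_layout: %s",
                     paste(format(lay, digits = 15), collapse = " ")), path)
  readr::write_tsv(as_tibble(m), path, na = "NA", col_names = TRUE,
                   append = TRUE)
  invisible(path)
}

#' @rdname write_profile_matrix
#' @export
read_profile_matrix <- function(path) {
  if (!file.exists(path)) abort(sprintf("matrix file not found: %s", path))
  first <- readr::read_lines(path, n_max = 1)
  lay <- c(0.1, 0.8, 0.1)
  if (length(first) && grepl("^# bin_layout:", first)) {
    lay <- as.numeric(strsplit(sub("^# bin_layout:\\s*", "", first), " +")[[1]])
  }
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0) abort(sprintf("%s: no header line", path))
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(header) < 2 || header[1] != "gene_id") {
    abort(sprintf("%s: malformed profile-matrix header", path))
  }
  n_bins <- length(header) - 1L
  if (!identical(header[-1], bin_labels(n_bins))) {
    abort(sprintf("%s: bin columns do not match expected labels p01..p%02d",
                  path, n_bins))
  }
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  if (any(lengths(rows) != length(header))) {
    bad <- which(lengths(rows) != length(header))[1]
    abort(sprintf("%s: row %d has %d fields, header has %d",
                  path, bad, lengths(rows)[bad], length(header)))
  }
  gene_id <- vapply(rows, `[[`, character(1), 1)
  # as.numeric (strtod) parses the shortest round-trip representation
  # written by write_tsv back to the identical double
  chr <- t(vapply(rows, function(r) r[-1], character(n_bins)))
  vals <- matrix(suppressWarnings(as.numeric(chr)),
                 nrow = length(rows), ncol = n_bins)
  profile_matrix(vals, gene_id, bin_layout = lay)
}

#' Read a two-column gene category file
#'
#' @param path TSV with columns `gene_id` and `category` (no header
#'   required; a `gene_id<TAB>category` header is tolerated), one
#'   membership per line.
#' @return tibble with `gene_id`, `category`.
#' @export
read_categories <- function(path) {
  if (!file.exists(path)) abort(sprintf("category file not found: %s", path))
  df <- readr::read_tsv(path, col_names = c("gene_id", "category"),
                        col_types = "cc", comment = "#", progress = FALSE)
  if (nrow(df) && identical(unlist(df[1, ], use.names = FALSE),
                            c("gene_id", "category"))) {
    df <- df[-1, ]
  }
  df
}

#' Read a ChIP-qPCR replicate table
#'
#' @param path CSV with columns `target`, `condition`, `replicate`,
#'   `ip_signal`, `input_signal` and optionally `input_fraction`
#'   (defaulted to 1 when absent).
#' @return tibble of replicate-level measurements.
#' @export
read_qpcr <- function(path) {
  if (!file.exists(path)) abort(sprintf("qPCR table not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("target", "condition", "replicate", "ip_signal", "input_signal")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort(sprintf("%s: missing columns: %s", path, paste(miss, collapse = ", ")))
  }
  if (!"input_fraction" %in% names(df)) df$input_fraction <- 1
  if (any(df$ip_signal < 0) || any(df$input_signal < 0)) {
    abort(sprintf("%s: qPCR signals must be non-negative", path))
  }
  if (any(df$input_fraction <= 0 | df$input_fraction > 1)) {
    abort(sprintf("%s: input_fraction must be in (0, 1]", path))
  }
  df
}
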