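#' Write an abundance matrix as TSV
#'
#' The first column is `feature_id`; the remaining column names are the time
#' points in hours. [read_abundance_tsv()] reads the format back.
#'
#' @param x an `abundance_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_abundance_tsv <- function(x, path) {
  stopifnot(inherits(x, "abundance_matrix"))
  df <- data.frame(feature_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an abundance matrix from TSV
#'
#' @param path TSV with a `feature_id` column and one column per time point,
#'   named by the time in hours.
#' @param kind `"exon_count"` or `"intron_coverage"`.
#' @return An `abundance_matrix`.
#' @export
read_abundance_tsv <- function(path, kind = c("exon_count", "intron_coverage")) {
  kind <- match.arg(kind)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"feature_id" %in% names(df)) stop("missing `feature_id` column in ", path)
  m <- as.matrix(df[, setdiff(names(df), "feature_id"), drop = FALSE])
  rownames(m) <- df$feature_id
  tp <- suppressWarnings(as.numeric(colnames(m)))
  if (anyNA(tp)) stop("column names of ", path, " must be time points in hours")
  abundance_matrix(m, tp, kind)
}

#' Write per-genome read totals as TSV
#' @param x a `genome_partition`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_partition_tsv <- function(x, path) {
  stopifnot(inherits(x, "genome_partition"))
  df <- data.frame(genome_label = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-genome read totals from TSV
#' @param path TSV with a `genome_label` column and one column per time point.
#' @return A `genome_partition`.
#' @export
read_partition_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"genome_label" %in% names(df)) stop("missing `genome_label` column in ", path)
  m <- as.matrix(df[, setdiff(names(df), "genome_label"), drop = FALSE])
  rownames(m) <- df$genome_label
  tp <- suppressWarnings(as.numeric(colnames(m)))
  if (anyNA(tp)) stop("column names of ", path, " must be time points in hours")
  genome_partition(m, tp)
}

#' Write a half-life table as TSV
#'
#' Columns: `gene_id`, `half_life_hours` (4 significant figures),
#' `lambda_per_hour`, `N0`, `gamma_per_hour`, `converged`, `rss`, `n_points`.
#'
#' @param fits data frame as returned by [fit_table()].
#' @param path output file path.
#' @param digits significant figures for the reported half-lives.
#' @return `path`, invisibly.
#' @export
write_half_lives_tsv <- function(fits, path, digits = 4) {
  out <- data.frame(
    gene_id = fits$gene_id,
    half_life_hours = signif(fits$half_life, digits),
    lambda_per_hour = fits$lambda,
    N0 = fits$N0,
    gamma_per_hour = fits$gamma,
    converged = fits$converged,
    rss = fits$rss,
    n_points = fits$n_points,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a half-life table written by [write_half_lives_tsv()]
#' @param path TSV path.
#' @return Data frame with at least `gene_id` and `half_life` columns.
#' @export
read_half_lives_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "half_life_hours") %in% names(df))) {
    stop("not a half-life table: ", path)
  }
  df$half_life <- df$half_life_hours
  df
}
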