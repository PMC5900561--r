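#' Abundance matrix over a labeling time course
#'
#' Container for per-feature abundance measurements across the time points of
#' a metabolic-labeling (or shutoff) experiment: integer exon counts per gene,
#' or real-valued mean per-base coverage per intron.
#'
#' @param values numeric matrix, features in rows (rownames are feature ids),
#'   time points in columns. All values must be non-negative.
#' @param time_points numeric vector of sampling times in hours, strictly
#'   increasing, one per column of `values`.
#' @param kind `"exon_count"` or `"intron_coverage"`.
#' @return An object of class `abundance_matrix` with fields `values`,
#'   `time_points` and `kind`.
#' @export
abundance_matrix <- function(values, time_points,
                             kind = c("exon_count", "intron_coverage")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (is.null(rownames(values))) {
    stop("`values` must carry feature ids as rownames")
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicated feature ids in `values`")
  }
  time_points <- as.numeric(time_points)
  if (ncol(values) != length(time_points)) {
    stop("ncol(values) must equal length(time_points)")
  }
  if (anyNA(values) || any(values < 0)) {
    stop("abundance values must be non-negative and non-missing")
  }
  if (length(time_points) > 1 && any(diff(time_points) <= 0)) {
    stop("time_points must be strictly increasing")
  }
  colnames(values) <- format(time_points, trim = TRUE)
  structure(list(values = values, time_points = time_points, kind = kind),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance_matrix [%s]: %d features x %d time points (%s h)\n",
              x$kind, nrow(x$values), length(x$time_points),
              paste(x$time_points, collapse = ", ")))
  invisible(x)
}

#' Feature ids of an abundance matrix
#' @param x an `abundance_matrix`.
#' @return Character vector of feature ids (rownames).
#' @export
feature_ids <- function(x) rownames(x$values)

#' Restrict an abundance matrix to a feature subset
#' @param x an `abundance_matrix`.
#' @param ids feature ids to retain (must all be present).
#' @return An `abundance_matrix` with only the requested rows, in the
#'   requested order.
#' @export
subset_features <- function(x, ids) {
  missing <- setdiff(ids, rownames(x$values))
  if (length(missing) > 0) {
    stop("feature ids absent from matrix: ", paste(utils::head(missing, 5), collapse = ", "))
  }
  abundance_matrix(x$values[ids, , drop = FALSE], x$time_points, x$kind)
}

#' Restrict an abundance matrix to a subset of time points
#' @param x an `abundance_matrix`.
#' @param keep numeric vector of time points (hours) to retain; must be a
#'   subset of `x$time_points`.
#' @return An `abundance_matrix` restricted to the kept columns.
#' @export
subset_time_points <- function(x, keep) {
  keep <- sort(as.numeric(keep))
  idx <- match(keep, x$time_points)
  if (anyNA(idx)) {
    stop("time points not present in matrix: ",
         paste(keep[is.na(idx)], collapse = ", "))
  }
  abundance_matrix(x$values[, idx, drop = FALSE], keep, x$kind)
}

#' Per-genome read totals across a time course
#'
#' For multi-organism spike-in designs each read is assigned to a source
#' genome (for example `human`, `fly`, `yeast`) by its chromosome; this
#' container holds the per-genome totals at each time point.
#'
#' @param values numeric matrix of non-negative totals, genome labels in rows,
#'   time points in columns.
#' @param time_points numeric vector of sampling times in hours.
#' @return An object of class `genome_partition`.
#' @export
genome_partition <- function(values, time_points) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("`values` must carry genome labels as rownames")
  time_points <- as.numeric(time_points)
  if (ncol(values) != length(time_points)) {
    stop("ncol(values) must equal length(time_points)")
  }
  if (anyNA(values) || any(values < 0)) stop("read totals must be non-negative")
  colnames(values) <- format(time_points, trim = TRUE)
  structure(list(values = values, time_points = time_points),
            class = "genome_partition")
}

#' @export
print.genome_partition <- function(x, ...) {
  cat(sprintf("genome_partition: %d genomes x %d time points\n",
              nrow(x$values), length(x$time_points)))
  print(x$values)
  invisible(x)
}

#' Normalized per-gene time series
#'
#' Exon signal divided, per time point, by a normalization factor (summed
#' well-behaved intron coverage, or spike-in genome read totals). Only the
#' ratio of a gene's series across time matters to the kinetic fit, so the
#' overall scale of the factors is arbitrary.
#'
#' @param values numeric matrix, genes x time points, of relative abundances.
#' @param time_points numeric vector of hours.
#' @param factors the per-time-point divisors actually used (all > 0).
#' @param mode `"intron"`, `"spikein"` or `"none"`.
#' @return An object of class `normalized_series`.
#' @export
normalized_series <- function(values, time_points, factors,
                              mode = c("intron", "spikein", "none")) {
  mode <- match.arg(mode)
  values <- as.matrix(values)
  time_points <- as.numeric(time_points)
  factors <- as.numeric(factors)
  if (is.null(rownames(values))) stop("`values` must carry gene ids as rownames")
  if (ncol(values) != length(time_points)) stop("shape mismatch: values vs time_points")
  if (length(factors) != length(time_points)) stop("shape mismatch: factors vs time_points")
  if (any(factors <= 0)) stop("normalization factors must all be > 0")
  if (anyNA(values) || any(values < 0)) stop("relative abundances must be non-negative")
  colnames(values) <- format(time_points, trim = TRUE)
  structure(list(values = values, time_points = time_points,
                 factors = factors, mode = mode),
            class = "normalized_series")
}

#' @export
print.normalized_series <- function(x, ...) {
  cat(sprintf("normalized_series [%s mode]: %d genes x %d time points\n",
              x$mode, nrow(x$values), length(x$time_points)))
  invisible(x)
}
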