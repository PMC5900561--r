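#' Experiment design for a labeling time course
#'
#' Validated bundle of the experimental and analysis parameters: the sampling
#' design, the doubling time controlling growth correction, the normalization
#' mode, multi-genome labels, library strandedness, and the filter/clustering
#' thresholds. Defaults follow the standard saturating-4SU design: sampling at
#' 1, 2, 4, 8, 12 and 24 h, a 24-h doubling time, gene filter of at least 1
#' read at every time point and 5 at one, intron mean-coverage floor 0.5, and
#' k-means with four clusters.
#'
#' @param time_points sampling times in hours, strictly increasing, >= 3.
#' @param doubling_time_hours cellular doubling time `delta` (> 0; `Inf` for
#'   non-dividing cells). Spike-in-mode fits use `gamma = ln(2)/delta`;
#'   intron-mode fits use `gamma = 0`.
#' @param normalization_mode `"intron"`, `"spikein"` or `"none"`.
#' @param genome_label_map optional chromosome -> genome label map.
#' @param spikein_labeled_label,spikein_unlabeled_label genome labels of the
#'   labeled and unlabeled spike-ins (required in spike-in mode).
#' @param strandedness library strandedness for exon counting.
#' @param min_count_all,min_count_any gene read filter thresholds.
#' @param min_intron_coverage intron mean-coverage floor.
#' @param min_spikein_reads per-time-point spike-in read floor.
#' @param k number of k-means clusters for intron selection.
#' @param seed seed for the k-means restarts.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(time_points = c(1, 2, 4, 8, 12, 24),
                              doubling_time_hours = 24,
                              normalization_mode = c("intron", "spikein", "none"),
                              genome_label_map = NULL,
                              spikein_labeled_label = NULL,
                              spikein_unlabeled_label = NULL,
                              strandedness = c("reverse", "forward", "unstranded"),
                              min_count_all = 1, min_count_any = 5,
                              min_intron_coverage = 0.5,
                              min_spikein_reads = 1000,
                              k = 4, seed = 1L) {
  normalization_mode <- match.arg(normalization_mode)
  strandedness <- match.arg(strandedness)
  time_points <- as.numeric(time_points)
  if (length(time_points) < 3) {
    stop("design needs >= 3 time points for fitting; got ", length(time_points))
  }
  if (any(diff(time_points) <= 0)) stop("time_points must be strictly increasing")
  if (is.na(doubling_time_hours) || doubling_time_hours <= 0) {
    stop("doubling_time_hours must be > 0 (Inf for non-dividing cells)")
  }
  if (normalization_mode == "spikein" && is.null(spikein_labeled_label)) {
    stop("spike-in mode requires spikein_labeled_label")
  }
  if (k < 1) stop("k must be >= 1")
  structure(list(
    time_points = time_points,
    doubling_time_hours = doubling_time_hours,
    normalization_mode = normalization_mode,
    genome_label_map = genome_label_map,
    spikein_labeled_label = spikein_labeled_label,
    spikein_unlabeled_label = spikein_unlabeled_label,
    strandedness = strandedness,
    min_count_all = min_count_all, min_count_any = min_count_any,
    min_intron_coverage = min_intron_coverage,
    min_spikein_reads = min_spikein_reads,
    k = k, seed = as.integer(seed)
  ), class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf(
    "experiment_design: t = {%s} h, %s normalization, doubling time %s h (gamma = %.4g /h)\n",
    paste(x$time_points, collapse = ", "), x$normalization_mode,
    format(x$doubling_time_hours), design_gamma(x)))
  invisible(x)
}

#' Growth-dilution rate implied by a design
#'
#' `ln(2)/doubling_time` in spike-in mode; 0 in intron mode (the endogenous
#' factor grows with the transcriptome, absorbing dilution) and in
#' unnormalized mode.
#'
#' @param design an `experiment_design`.
#' @return Growth-dilution rate in per-hour units.
#' @export
design_gamma <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  if (design$normalization_mode == "spikein") {
    growth_rate(design$doubling_time_hours)
  } else {
    0
  }
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the half-life pipeline on quantified matrices
#'
#' Executes filter -> normalize -> fit on precomputed abundance matrices:
#' genes are filtered by read support; normalization factors come either from
#' the k-means-selected well-behaved intron set (intron mode, `gamma = 0`) or
#' from spike-in genome totals (spike-in mode,
#' `gamma = ln(2)/doubling time`); the bounded-growth model is fit per gene.
#' Stage failures propagate with the stage named; when an output directory is
#' given, partial outputs are removed on failure.
#'
#' @param design an [experiment_design()].
#' @param exon_counts `abundance_matrix` of gene-level exon counts.
#' @param intron_coverage `abundance_matrix` of intron mean coverage
#'   (required in intron mode).
#' @param partition [genome_partition()] of per-genome read totals (required
#'   in spike-in mode).
#' @param output_dir optional directory for the TSV outputs (`half_lives.tsv`,
#'   `normalization_factors.tsv`, intron cluster report, `run_metadata.tsv`).
#' @param weights weighting scheme for the fits.
#' @param quiet suppress progress messages.
#' @return List of class `druid_run`: `half_lives` (fit table), `series`
#'   (the [normalized_series()]), `factors`, `cluster_report` (intron mode),
#'   `stage_counts`, `design`.
#' @export
run_pipeline <- function(design, exon_counts, intron_coverage = NULL,
                         partition = NULL, output_dir = NULL,
                         weights = c("poisson", "uniform"), quiet = FALSE) {
  stopifnot(inherits(design, "experiment_design"))
  weights <- match.arg(weights)
  mode <- design$normalization_mode

  run_stage("validate", {
    stopifnot(inherits(exon_counts, "abundance_matrix"))
    if (!isTRUE(all.equal(exon_counts$time_points, design$time_points))) {
      stop("exon count time points do not match the design")
    }
    if (mode == "intron") {
      if (is.null(intron_coverage)) stop("intron mode requires intron_coverage")
      if (!isTRUE(all.equal(intron_coverage$time_points, design$time_points))) {
        stop("intron coverage time points do not match the design")
      }
    }
    if (mode == "spikein" && is.null(partition)) {
      stop("spike-in mode requires a genome partition")
    }
  })

  filtered <- run_stage("filter",
    filter_genes(exon_counts, design$min_count_all, design$min_count_any))

  cluster_report <- NULL
  factors <- run_stage("normalize", {
    if (mode == "intron") {
      fi <- filter_introns(intron_coverage, design$min_intron_coverage)
      cluster_report <- cluster_and_select_introns(fi, k = design$k,
                                                   seed = design$seed)
      intron_normalization_factors(fi, cluster_report$selected_introns)
    } else if (mode == "spikein") {
      spikein_normalization_factors(partition, design$spikein_labeled_label,
                                    design$min_spikein_reads)
    } else {
      stats::setNames(rep(1, length(design$time_points)),
                      format(design$time_points, trim = TRUE))
    }
  })
  series <- run_stage("normalize", normalize_abundance(filtered, factors, mode))

  fits <- run_stage("fit",
    fit_table(series, gamma = design_gamma(design), weights = weights,
              quiet = quiet))

  stage_counts <- c(input = nrow(exon_counts$values),
                    filtered = nrow(filtered$values),
                    converged = sum(fits$converged))
  if (!quiet) {
    message(sprintf("run_pipeline [%s]: %d genes in, %d after filters, %d with half-lives",
                    mode, stage_counts[1], stage_counts[2], stage_counts[3]))
  }

  res <- structure(list(half_lives = fits, series = series, factors = factors,
                        cluster_report = cluster_report,
                        stage_counts = stage_counts, design = design),
                   class = "druid_run")
  if (!is.null(output_dir)) {
    written <- character(0)
    tryCatch({
      dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
      f <- file.path(output_dir, "half_lives.tsv")
      write_half_lives_tsv(fits, f); written <- c(written, f)
      f <- file.path(output_dir, "normalization_factors.tsv")
      utils::write.table(
        data.frame(time_hours = design$time_points, factor = as.numeric(factors)),
        f, sep = "\t", quote = FALSE, row.names = FALSE)
      written <- c(written, f)
      if (!is.null(cluster_report)) {
        write_cluster_report(cluster_report, output_dir)
        written <- c(written, file.path(output_dir, c("introns_selected.tsv",
                                                      "cluster_centroids.tsv")))
      }
      f <- file.path(output_dir, "run_metadata.tsv")
      meta <- data.frame(
        key = c("druidr_version", "normalization_mode", "gamma_per_hour",
                "doubling_time_hours", "time_points_hours", "weights", "seed",
                "k", "genes_input", "genes_filtered", "genes_converged",
                "selected_introns"),
        value = c(as.character(utils::packageVersion("druidr")), mode,
                  format(design_gamma(design)),
                  format(design$doubling_time_hours),
                  paste(design$time_points, collapse = ","), weights,
                  design$seed, design$k, stage_counts[1], stage_counts[2],
                  stage_counts[3],
                  if (is.null(cluster_report)) NA else
                    length(cluster_report$selected_introns)),
        stringsAsFactors = FALSE)
      utils::write.table(meta, f, sep = "\t", quote = FALSE, row.names = FALSE)
      written <- c(written, f)
    }, error = function(e) {
      unlink(written)
      stop("stage 'report' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  res
}

#' Re-run normalization and fitting on a subset of time points
#'
#' Restricts the matrices (and partition) to the kept time points and re-runs
#' the pipeline; used to check how few time points suffice (three — e.g. 1, 8
#' and 24 h — determine the two-parameter model).
#'
#' @param design an [experiment_design()].
#' @param keep time points (hours) to retain; a subset of the design's, with
#'   at least 3 elements.
#' @inheritParams run_pipeline
#' @return A `druid_run` for the reduced design.
#' @export
ablate_time_points <- function(design, keep, exon_counts,
                               intron_coverage = NULL, partition = NULL,
                               output_dir = NULL,
                               weights = c("poisson", "uniform"),
                               quiet = FALSE) {
  stopifnot(inherits(design, "experiment_design"))
  keep <- sort(as.numeric(keep))
  if (length(keep) < 3) stop("need >= 3 retained time points")
  if (!all(keep %in% design$time_points)) {
    stop("kept time points must be a subset of the design's")
  }
  idx <- match(keep, design$time_points)
  design2 <- design
  design2$time_points <- keep
  exon2 <- subset_time_points(exon_counts, keep)
  intron2 <- if (!is.null(intron_coverage)) {
    subset_time_points(intron_coverage, keep)
  } else NULL
  part2 <- if (!is.null(partition)) {
    genome_partition(partition$values[, idx, drop = FALSE], keep)
  } else NULL
  run_pipeline(design2, exon2, intron2, part2, output_dir = output_dir,
               weights = weights, quiet = quiet)
}
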