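#' Filter genes by minimum read support
#'
#' Retains genes with at least `min_all` mapped reads at every time point and
#' at least `min_any` mapped reads at one or more time points (defaults 1 and
#' 5). Genes failing either rule carry too little signal for a stable kinetic
#' fit.
#'
#' @param exon_counts an `abundance_matrix` of kind `exon_count`.
#' @param min_all minimum count required at every time point.
#' @param min_any count required at at least one time point.
#' @return The filtered `abundance_matrix`.
#' @export
filter_genes <- function(exon_counts, min_all = 1, min_any = 5) {
  stopifnot(inherits(exon_counts, "abundance_matrix"))
  if (exon_counts$kind != "exon_count") stop("filter_genes expects exon counts")
  v <- exon_counts$values
  keep <- apply(v, 1, function(x) all(x >= min_all) && any(x >= min_any))
  if (!any(keep)) {
    stop(sprintf(
      "no genes pass filters (>= %g reads at every time point, >= %g at one)",
      min_all, min_any))
  }
  abundance_matrix(v[keep, , drop = FALSE], exon_counts$time_points,
                   exon_counts$kind)
}

#' Filter introns by mean coverage
#'
#' Retains introns whose mean per-base coverage, averaged across the time
#' points, is at least `min_mean` (default 0.5 reads).
#'
#' @param intron_cov an `abundance_matrix` of kind `intron_coverage`.
#' @param min_mean minimum mean coverage across time points.
#' @return The filtered `abundance_matrix`.
#' @export
filter_introns <- function(intron_cov, min_mean = 0.5) {
  stopifnot(inherits(intron_cov, "abundance_matrix"))
  if (intron_cov$kind != "intron_coverage") {
    stop("filter_introns expects intron coverage")
  }
  keep <- rowMeans(intron_cov$values) >= min_mean
  if (!any(keep)) {
    stop(sprintf("no introns pass filters (mean coverage >= %g)", min_mean))
  }
  abundance_matrix(intron_cov$values[keep, , drop = FALSE],
                   intron_cov$time_points, intron_cov$kind)
}

#' Cluster intron time profiles and select the well-behaved set
#'
#' Rapidly equilibrating introns are at their labeled steady state throughout
#' the time course, so their share of a fixed-depth library falls as the
#' labeled mRNA pool grows: the expected profile is non-increasing in time.
#' Retained or misannotated introns instead rise like mRNAs. Profiles are
#' divided by their own mean (shape, not magnitude), clustered with k-means
#' (default `k = 4`, seeded, 25 restarts), and each cluster centroid is scored
#' by its Spearman correlation with time: the most negative score wins, with
#' the total positive increment `sum(max(0, diff(centroid)))` breaking ties.
#' The winning cluster's introns are the "well-behaved" normalization set.
#'
#' Rows are sorted by intron id before clustering, so the result is invariant
#' to input order. With fewer than `k` introns (or fewer distinct profiles
#' than `k`) the effective number of clusters is reduced, with a warning, down
#' to a single all-intron cluster.
#'
#' @param intron_cov a filtered `abundance_matrix` of kind `intron_coverage`.
#' @param k number of clusters.
#' @param seed RNG seed for the k-means restarts.
#' @param nstart number of seeded k-means restarts.
#' @param select_cluster optional manual override: the index of the cluster to
#'   select instead of the automatic non-increasing criterion.
#' @return An `intron_cluster_report`: `membership` data frame (`intron_id`,
#'   `cluster`, `selected`), `centroids` (k x time matrix of mean scaled
#'   profiles), `selection_scores` data frame (`cluster`, `spearman_vs_time`,
#'   `positive_increment`), `selected_cluster`, and `selected_introns`.
#' @export
cluster_and_select_introns <- function(intron_cov, k = 4, seed = 1L,
                                       nstart = 25, select_cluster = NULL) {
  stopifnot(inherits(intron_cov, "abundance_matrix"))
  v <- intron_cov$values
  v <- v[order(rownames(v)), , drop = FALSE]
  tp <- intron_cov$time_points
  m <- rowMeans(v)
  scale_by <- ifelse(m > 0, m, 1)  # degenerate all-zero profiles left as-is
  profiles <- v / scale_by

  n_distinct <- nrow(unique(profiles))
  k_eff <- min(k, nrow(profiles), n_distinct)
  if (k_eff < k) {
    warning(sprintf(
      "only %d introns (%d distinct profiles); clustering with k = %d",
      nrow(profiles), n_distinct, k_eff))
  }

  if (k_eff <= 1) {
    cluster <- rep(1L, nrow(profiles))
    centroids <- matrix(colMeans(profiles), nrow = 1,
                        dimnames = list(NULL, colnames(profiles)))
  } else {
    # seeded restarts with distinct initial centers: robust to the many
    # (near-)duplicate profiles an equilibrated intron set produces
    set.seed(seed)
    uniq <- unique(profiles)
    km <- NULL
    for (i in seq_len(nstart)) {
      cen <- uniq[sample.int(nrow(uniq), k_eff), , drop = FALSE]
      cand <- tryCatch(
        suppressWarnings(stats::kmeans(profiles, centers = cen,
                                       iter.max = 100, algorithm = "Lloyd")),
        error = function(e) NULL)
      if (!is.null(cand) && (is.null(km) || cand$tot.withinss < km$tot.withinss)) {
        km <- cand
      }
    }
    if (is.null(km)) {
      km <- suppressWarnings(stats::kmeans(profiles, centers = k_eff,
                                           iter.max = 100))
    }
    cluster <- km$cluster
    centroids <- km$centers
  }

  scores <- data.frame(
    cluster = seq_len(nrow(centroids)),
    spearman_vs_time = apply(centroids, 1, function(cen) {
      s <- suppressWarnings(stats::cor(cen, tp, method = "spearman"))
      if (is.na(s)) 0 else s
    }),
    positive_increment = apply(centroids, 1, function(cen) {
      sum(pmax(diff(cen), 0))
    })
  )
  selected <- if (!is.null(select_cluster)) {
    if (!select_cluster %in% scores$cluster) stop("select_cluster out of range")
    as.integer(select_cluster)
  } else {
    ord <- order(scores$spearman_vs_time, scores$positive_increment)
    scores$cluster[ord[1]]
  }

  membership <- data.frame(intron_id = rownames(profiles), cluster = cluster,
                           selected = cluster == selected,
                           stringsAsFactors = FALSE)
  structure(list(
    membership = membership,
    centroids = centroids,
    selection_scores = scores,
    selected_cluster = selected,
    selected_introns = membership$intron_id[membership$selected],
    k = k_eff, seed = seed
  ), class = "intron_cluster_report")
}

#' @export
print.intron_cluster_report <- function(x, ...) {
  cat(sprintf(
    "intron_cluster_report: %d introns, k = %d, selected cluster %d (%d introns)\n",
    nrow(x$membership), x$k, x$selected_cluster, length(x$selected_introns)))
  print(x$selection_scores)
  invisible(x)
}

#' Per-time-point normalization factors from the selected intron set
#'
#' `factor(t)` is the summed coverage of the well-behaved introns at time `t`.
#'
#' @param intron_cov an `abundance_matrix` of kind `intron_coverage`.
#' @param selected character vector of selected intron ids (non-empty, all
#'   present in the matrix).
#' @return Numeric vector of factors, one per time point, all > 0.
#' @export
intron_normalization_factors <- function(intron_cov, selected) {
  stopifnot(inherits(intron_cov, "abundance_matrix"))
  if (length(selected) == 0) stop("selected intron set is empty")
  missing <- setdiff(selected, rownames(intron_cov$values))
  if (length(missing) > 0) {
    stop("selected introns absent from matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  f <- colSums(intron_cov$values[selected, , drop = FALSE])
  bad <- which(f <= 0)
  if (length(bad) > 0) {
    stop("zero intron normalization factor at time point(s) ",
         paste(intron_cov$time_points[bad], collapse = ", "),
         " h: normalization undefined")
  }
  stats::setNames(as.numeric(f), colnames(intron_cov$values))
}

#' Per-time-point normalization factors from spike-in genome totals
#'
#' `factor(t)` is the total number of reads assigned to the spike-in genome at
#' time `t`. Time points with fewer than `min_reads` spike-in reads make the
#' factor too noisy to use and raise the "insufficient spike-in reads"
#' failure that characterizes recalcitrant data sets.
#'
#' @param partition a `genome_partition`.
#' @param spikein_label genome label of the labeled spike-in.
#' @param min_reads minimum spike-in reads required at every time point
#'   (default 1000, about a 3\% counting CV; zero reads always fail).
#' @return Numeric vector of factors, one per time point.
#' @export
spikein_normalization_factors <- function(partition, spikein_label,
                                          min_reads = 1000) {
  stopifnot(inherits(partition, "genome_partition"))
  if (!spikein_label %in% rownames(partition$values)) {
    stop("spike-in genome label not present in partition: ", spikein_label)
  }
  f <- partition$values[spikein_label, ]
  bad <- which(f < max(min_reads, .Machine$double.xmin))
  if (length(bad) > 0) {
    stop("insufficient spike-in reads (< ", min_reads, ") at time point(s) ",
         paste(partition$time_points[bad], collapse = ", "), " h")
  }
  stats::setNames(as.numeric(f), colnames(partition$values))
}

#' Normalize exon counts by per-time-point factors
#'
#' `relative_abundance[g, t] = count[g, t] / factor(t)`. The factors actually
#' used and the normalization mode are recorded in the result.
#'
#' @param exon_counts an `abundance_matrix` of kind `exon_count`.
#' @param factors numeric vector of per-time-point divisors, all > 0, aligned
#'   with the matrix columns.
#' @param mode `"intron"`, `"spikein"` or `"none"`.
#' @return A [normalized_series()].
#' @export
normalize_abundance <- function(exon_counts, factors,
                                mode = c("intron", "spikein", "none")) {
  mode <- match.arg(mode)
  stopifnot(inherits(exon_counts, "abundance_matrix"))
  factors <- as.numeric(factors)
  if (length(factors) != length(exon_counts$time_points)) {
    stop("shape mismatch: ", length(factors), " factors for ",
         length(exon_counts$time_points), " time points")
  }
  if (any(factors <= 0)) stop("normalization factors must all be > 0")
  rel <- sweep(exon_counts$values, 2, factors, "/")
  normalized_series(rel, exon_counts$time_points, factors, mode)
}

#' Purification enrichment QC from two-organism spike-ins
#'
#' With a labeled exogenous spike-in (e.g. 4SU-labeled fly RNA) and an
#' unlabeled one (e.g. yeast RNA), the ratio of labeled to unlabeled spike-in
#' reads in the purified sample, divided by the same ratio in the unpurified
#' sample, measures the fold enrichment achieved by the biotin-streptavidin
#' selection. Values around 100 indicate ~1\% nonspecific background.
#'
#' @param purified,unpurified `genome_partition`s over the same genome labels
#'   and time points.
#' @param labeled_label genome label of the labeled spike-in.
#' @param unlabeled_label genome label of the unlabeled spike-in.
#' @return Named numeric vector of per-time-point enrichment folds.
#' @export
enrichment_qc <- function(purified, unpurified, labeled_label,
                          unlabeled_label) {
  stopifnot(inherits(purified, "genome_partition"),
            inherits(unpurified, "genome_partition"))
  for (lab in c(labeled_label, unlabeled_label)) {
    if (!lab %in% rownames(purified$values) ||
        !lab %in% rownames(unpurified$values)) {
      stop("genome label missing from a partition: ", lab)
    }
  }
  pu_l <- purified$values[labeled_label, ]
  pu_u <- purified$values[unlabeled_label, ]
  un_l <- unpurified$values[labeled_label, ]
  un_u <- unpurified$values[unlabeled_label, ]
  if (any(pu_u == 0) || any(un_u == 0) || any(un_l == 0)) {
    stop("zero denominator in enrichment computation")
  }
  stats::setNames((pu_l / pu_u) / (un_l / un_u), colnames(purified$values))
}

#' Write an intron cluster report to TSV files
#'
#' Writes `introns_selected.tsv` (intron id, cluster, selected flag) and
#' `cluster_centroids.tsv` (cluster, scores, centroid profile) into `dir`.
#'
#' @param report an `intron_cluster_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cluster_report <- function(report, dir) {
  stopifnot(inherits(report, "intron_cluster_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$membership, file.path(dir, "introns_selected.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cen <- data.frame(report$selection_scores,
                    selected = report$selection_scores$cluster ==
                      report$selected_cluster,
                    report$centroids, check.names = FALSE)
  utils::write.table(cen, file.path(dir, "cluster_centroids.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
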