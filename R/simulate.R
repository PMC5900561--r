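#' Ground truth for a simulated labeling experiment
#'
#' Draws per-gene decay constants and steady-state abundances, attaches
#' intron species to host genes, and fixes the experiment-level constants
#' (growth, spike-in mass fractions, purification carryover, sequencing
#' depth). The object is consumed by [simulate_labeling_experiment()],
#' [simulate_shutoff_experiment()] and [simulate_recalcitrant()].
#'
#' Defaults describe a quiescent mammalian culture labeled at saturating
#' 4SU: gene half-lives log-uniform between 15 min and 36 h; steady-state
#' abundances spanning two decades; introns at roughly a fifth of their host
#' gene's abundance so that intron-mapping reads make up ~20\% of early
#' libraries; well-behaved introns with 2-min half-lives (equilibrated long
#' before the first time point); 60\% of expressed introns "misbehaving"
#' (retained or misannotated, so they accumulate with mRNA-like long
#' half-lives); labeled and unlabeled spike-ins each at 2\% of total RNA
#' mass; 1\% unlabeled carryover through the purification; 2e6 reads per
#' time point.
#'
#' @param n_genes number of genes.
#' @param n_introns number of quantified intron species.
#' @param doubling_time cellular doubling time in hours; `Inf` (default)
#'   means non-dividing cells, i.e. growth-dilution rate 0.
#' @param lambda_range range of gene decay constants (per hour); sampled
#'   log-uniformly.
#' @param abundance_range range of steady-state gene abundances (arbitrary
#'   mass units); sampled log-uniformly.
#' @param intron_ratio_range intron:host steady-state abundance ratio range;
#'   sampled log-uniformly.
#' @param misbehaving_frac fraction of introns given mRNA-like (slow) decay.
#' @param misbehaving_lambda_range decay-constant range for misbehaving
#'   introns (default: half-lives 2-36 h).
#' @param intron_half_life half-life (hours) of well-behaved introns.
#' @param depth sequencing depth per time point (reads).
#' @param spike_labeled_frac labeled spike-in mass as a fraction of total RNA.
#' @param spike_unlabeled_frac unlabeled spike-in mass fraction.
#' @param carryover fraction of unlabeled RNA carried through purification.
#' @param read_length read length (nt), used to convert intron read counts to
#'   mean per-base coverage.
#' @param intron_length nominal intron length (nt), the coverage divisor.
#' @param seed RNG seed for the truth draw (also the default simulation seed).
#' @return An object of class `simulation_truth` with elements `genes`
#'   (gene_id, synthesis, lambda, half_life, abundance), `introns`
#'   (intron_id, host_gene, abundance, lambda, misbehaving), `gamma`, and the
#'   experiment-level constants.
#' @export
simulation_truth <- function(n_genes = 500, n_introns = 300,
                             doubling_time = Inf,
                             lambda_range = c(log(2) / 36, log(2) / 0.25),
                             abundance_range = c(1, 100),
                             intron_ratio_range = c(0.05, 0.5),
                             misbehaving_frac = 0.6,
                             misbehaving_lambda_range = c(log(2) / 36, log(2) / 2),
                             intron_half_life = 1 / 30,
                             depth = 2e6,
                             spike_labeled_frac = 0.02,
                             spike_unlabeled_frac = 0.02,
                             carryover = 0.01,
                             read_length = 50,
                             intron_length = 1000,
                             seed = 1L) {
  stopifnot(n_genes >= 1, n_introns >= 0, depth > 0, carryover >= 0,
            intron_half_life > 0, all(lambda_range > 0))
  gamma <- growth_rate(doubling_time)
  set.seed(seed)

  lam <- exp(stats::runif(n_genes, log(lambda_range[1]), log(lambda_range[2])))
  ab <- exp(stats::runif(n_genes, log(abundance_range[1]),
                         log(abundance_range[2])))
  genes <- data.frame(
    gene_id = sprintf("g%04d", seq_len(n_genes)),
    synthesis = ab * (lam + gamma),
    lambda = lam,
    half_life = log(2) / lam,
    abundance = ab,
    stringsAsFactors = FALSE
  )

  introns <- NULL
  if (n_introns > 0) {
    host <- sample.int(n_genes, n_introns, replace = TRUE)
    ratio <- exp(stats::runif(n_introns, log(intron_ratio_range[1]),
                              log(intron_ratio_range[2])))
    misbehaving <- seq_len(n_introns) %in%
      sample.int(n_introns, round(misbehaving_frac * n_introns))
    ilam <- ifelse(
      misbehaving,
      exp(stats::runif(n_introns, log(misbehaving_lambda_range[1]),
                       log(misbehaving_lambda_range[2]))),
      log(2) / intron_half_life
    )
    introns <- data.frame(
      intron_id = sprintf("i%04d", seq_len(n_introns)),
      host_gene = genes$gene_id[host],
      abundance = ratio * genes$abundance[host],
      lambda = ilam,
      misbehaving = misbehaving,
      stringsAsFactors = FALSE
    )
  }

  structure(list(
    genes = genes, introns = introns, gamma = gamma,
    doubling_time = doubling_time, depth = depth,
    spike_labeled_frac = spike_labeled_frac,
    spike_unlabeled_frac = spike_unlabeled_frac,
    carryover = carryover, read_length = read_length,
    intron_length = intron_length, seed = seed
  ), class = "simulation_truth")
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat(sprintf(
    "simulation_truth: %d genes, %d introns, gamma = %.4g /h, depth = %g\n",
    nrow(x$genes), if (is.null(x$introns)) 0 else nrow(x$introns),
    x$gamma, x$depth))
  invisible(x)
}

# Species masses in the purified (labeled) pool and the unpurified extract at
# one time point. The labeled pool of species i approaches its steady state
# as 1 - exp(-(lambda_i + gamma)*t) per cell, and culture totals scale as
# exp(gamma*t); unlabeled totals decay as exp(-lambda_i*t). Spike-ins are
# added at a constant ratio to the total extracted RNA mass.
labeling_composition <- function(truth, t, spike_multiplier = 1) {
  g <- truth$genes
  i <- truth$introns
  gam <- truth$gamma
  grow <- exp(gam * t)
  g_lab <- g$abundance * (1 - exp(-(g$lambda + gam) * t)) * grow
  g_unl <- g$abundance * exp(-g$lambda * t)
  if (!is.null(i)) {
    i_lab <- i$abundance * (1 - exp(-(i$lambda + gam) * t)) * grow
    i_unl <- i$abundance * exp(-i$lambda * t)
  } else {
    i_lab <- i_unl <- numeric(0)
  }
  total_rna <- grow * (sum(g$abundance) + sum(if (is.null(i)) 0 else i$abundance))
  sp_lab <- truth$spike_labeled_frac * total_rna * spike_multiplier
  sp_unl <- truth$spike_unlabeled_frac * total_rna
  co <- truth$carryover
  list(
    purified = list(genes = g_lab + co * g_unl,
                    introns = i_lab + co * i_unl,
                    spike_labeled = sp_lab,
                    spike_unlabeled = co * sp_unl),
    unpurified = list(genes = g_lab + g_unl,
                      introns = i_lab + i_unl,
                      spike_labeled = sp_lab,
                      spike_unlabeled = sp_unl)
  )
}

# Fixed-depth compositional sampling of one library.
sample_library <- function(masses, depth, sampling) {
  frac <- masses / sum(masses)
  if (sampling == "expected") {
    depth * frac
  } else {
    as.numeric(stats::rmultinom(1, size = depth, prob = frac))
  }
}

#' Simulate an approach-to-equilibrium labeling experiment
#'
#' Generates the purified-library read counts of a metabolic-labeling time
#' course from a [simulation_truth()]: per-cell labeled pools approach their
#' steady states at rate `lambda + gamma`, culture totals grow as
#' `exp(gamma*t)`, unlabeled pools decay at `lambda`, spike-ins are added at a
#' constant ratio to total extracted RNA, purification retains the labeled
#' pool plus a `carryover` fraction of unlabeled RNA, and each library is a
#' fixed-depth multinomial draw over the resulting composition
#' (`sampling = "expected"` disables the draw and returns expected counts).
#'
#' @param truth a `simulation_truth`.
#' @param time_points sampling times in hours (default the 1, 2, 4, 8, 12,
#'   24 h design).
#' @param sampling `"multinomial"` (default) or `"expected"` (noise off).
#' @param seed RNG seed for the sampling draws; defaults to the truth's seed.
#' @param spike_multiplier optional per-time-point multiplier of the labeled
#'   spike-in mass (used by [simulate_recalcitrant()]).
#' @return A list of class `druid_simulation`: `exon_counts` and
#'   `intron_coverage` ([abundance_matrix()]s), `partition` and
#'   `unpurified_partition` ([genome_partition()]s over labels `target`,
#'   `spike_labeled`, `spike_unlabeled`), and the `truth` echo.
#' @export
simulate_labeling_experiment <- function(truth,
                                         time_points = c(1, 2, 4, 8, 12, 24),
                                         sampling = c("multinomial", "expected"),
                                         seed = NULL,
                                         spike_multiplier = NULL) {
  stopifnot(inherits(truth, "simulation_truth"))
  sampling <- match.arg(sampling)
  time_points <- as.numeric(time_points)
  if (length(time_points) < 3) stop("need >= 3 time points")
  if (any(diff(time_points) <= 0) || any(time_points <= 0)) {
    stop("time points must be positive and strictly increasing")
  }
  if (is.null(spike_multiplier)) spike_multiplier <- rep(1, length(time_points))
  if (length(spike_multiplier) != length(time_points)) {
    stop("spike_multiplier must match time_points")
  }
  if (is.null(seed)) seed <- truth$seed
  set.seed(seed)

  ng <- nrow(truth$genes)
  ni <- if (is.null(truth$introns)) 0 else nrow(truth$introns)
  tcount <- length(time_points)
  exon <- matrix(0, ng, tcount, dimnames = list(truth$genes$gene_id, NULL))
  intr <- matrix(0, max(ni, 0), tcount,
                 dimnames = list(truth$introns$intron_id, NULL))
  part <- matrix(0, 3, tcount,
                 dimnames = list(c("target", "spike_labeled", "spike_unlabeled"),
                                 NULL))
  unpart <- part

  for (j in seq_along(time_points)) {
    comp <- labeling_composition(truth, time_points[j], spike_multiplier[j])
    pu <- comp$purified
    masses <- c(pu$genes, pu$introns, pu$spike_labeled, pu$spike_unlabeled)
    reads <- sample_library(masses, truth$depth, sampling)
    exon[, j] <- reads[seq_len(ng)]
    if (ni > 0) intr[, j] <- reads[ng + seq_len(ni)]
    part[, j] <- c(sum(reads[seq_len(ng + ni)]), reads[ng + ni + 1],
                   reads[ng + ni + 2])
    un <- comp$unpurified
    umasses <- c(sum(un$genes) + sum(un$introns), un$spike_labeled,
                 un$spike_unlabeled)
    unpart[, j] <- sample_library(umasses, truth$depth, sampling)
  }

  intron_cov <- if (ni > 0) {
    abundance_matrix(intr * truth$read_length / truth$intron_length,
                     time_points, "intron_coverage")
  } else NULL

  structure(list(
    exon_counts = abundance_matrix(exon, time_points, "exon_count"),
    intron_coverage = intron_cov,
    partition = genome_partition(part, time_points),
    unpurified_partition = genome_partition(unpart, time_points),
    truth = truth, sampling = sampling, seed = seed,
    spike_multiplier = spike_multiplier
  ), class = "druid_simulation")
}

#' Simulate a transcription-shutoff experiment
#'
#' After transcription inhibition at `t = 0` each gene's pool decays as
#' `N0 * exp(-lambda*t)`. A spike-in is added at constant mass per
#' cell-equivalent of extracted RNA, so the spike-normalized series is
#' proportional to the decaying pool. Libraries are fixed-depth multinomial
#' draws as in [simulate_labeling_experiment()].
#'
#' @inheritParams simulate_labeling_experiment
#' @param time_points sampling times in hours; must include 0.
#' @return A list of class `druid_simulation`: `exon_counts` and a
#'   `partition` over labels `target` and `spike_labeled`.
#' @export
simulate_shutoff_experiment <- function(truth,
                                        time_points = c(0, 1, 2, 4, 8, 12, 24),
                                        sampling = c("multinomial", "expected"),
                                        seed = NULL) {
  stopifnot(inherits(truth, "simulation_truth"))
  sampling <- match.arg(sampling)
  time_points <- as.numeric(time_points)
  if (length(time_points) < 3) stop("need >= 3 time points")
  if (!any(time_points == 0)) stop("shutoff design must include t = 0")
  if (any(diff(time_points) <= 0)) stop("time points must be strictly increasing")
  if (is.null(seed)) seed <- truth$seed
  set.seed(seed)

  g <- truth$genes
  spike_mass <- truth$spike_labeled_frac * sum(g$abundance)
  ng <- nrow(g)
  tcount <- length(time_points)
  exon <- matrix(0, ng, tcount, dimnames = list(g$gene_id, NULL))
  part <- matrix(0, 2, tcount,
                 dimnames = list(c("target", "spike_labeled"), NULL))
  for (j in seq_along(time_points)) {
    masses <- c(g$abundance * exp(-g$lambda * time_points[j]), spike_mass)
    reads <- sample_library(masses, truth$depth, sampling)
    exon[, j] <- reads[seq_len(ng)]
    part[, j] <- c(sum(reads[seq_len(ng)]), reads[ng + 1])
  }
  structure(list(
    exon_counts = abundance_matrix(exon, time_points, "exon_count"),
    intron_coverage = NULL,
    partition = genome_partition(part, time_points),
    truth = truth, sampling = sampling, seed = seed
  ), class = "druid_simulation")
}

#' Simulate a recalcitrant (spike-in-compromised) data set
#'
#' Reproduces the two failure signatures that make labeling experiments
#' unusable under spike-in normalization while leaving the endogenous intron
#' signal intact:
#' * `few_spikein_reads`: the labeled spike-in mass fraction is scaled down
#'   100-fold, so spike-in read totals fall below a usable floor;
#' * `biased_spikein`: the labeled spike-in mass at each time point is
#'   multiplied by a time-dependent distortion
#'   `exp(drift * t + N(0, jitter_sd^2))`, emulating abnormal spike-in
#'   behavior (progressive degradation or labeling bias) that corrupts the
#'   factors. The default is a pure systematic drift of 0.15/h (a 36-fold
#'   mis-scaling across a 24-h course); `jitter_sd` adds per-time-point
#'   lognormal scatter on top.
#'
#' @inheritParams simulate_labeling_experiment
#' @param mode `"few_spikein_reads"` or `"biased_spikein"`.
#' @param drift systematic per-hour log-drift of the biased spike-in mass.
#' @param jitter_sd per-time-point lognormal jitter of the biased spike-in.
#' @return As [simulate_labeling_experiment()]; the applied multiplier is in
#'   the `spike_multiplier` element.
#' @export
simulate_recalcitrant <- function(truth,
                                  mode = c("few_spikein_reads", "biased_spikein"),
                                  time_points = c(1, 2, 4, 8, 12, 24),
                                  sampling = c("multinomial", "expected"),
                                  seed = NULL, drift = 0.15, jitter_sd = 0) {
  stopifnot(inherits(truth, "simulation_truth"))
  mode <- match.arg(mode)
  sampling <- match.arg(sampling)
  if (is.null(seed)) seed <- truth$seed
  set.seed(seed)
  mult <- if (mode == "few_spikein_reads") {
    rep(0.01, length(time_points))
  } else {
    exp(drift * time_points + stats::rnorm(length(time_points), 0, jitter_sd))
  }
  # hand the library sampling a distinct, deterministic seed
  simulate_labeling_experiment(truth, time_points, sampling,
                               seed = seed + 1L, spike_multiplier = mult)
}

#' Write simulator outputs to a directory
#'
#' Writes the same TSV formats the quantification stage produces
#' (`exon_counts.tsv`, `intron_coverage.tsv`, `genome_totals.tsv`,
#' `unpurified_genome_totals.tsv`) plus `truth.tsv` (gene id, true half-life,
#' synthesis rate).
#'
#' @param sim a `druid_simulation`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation_tsv <- function(sim, dir) {
  stopifnot(inherits(sim, "druid_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_abundance_tsv(sim$exon_counts, file.path(dir, "exon_counts.tsv"))
  if (!is.null(sim$intron_coverage)) {
    write_abundance_tsv(sim$intron_coverage, file.path(dir, "intron_coverage.tsv"))
  }
  write_partition_tsv(sim$partition, file.path(dir, "genome_totals.tsv"))
  if (!is.null(sim$unpurified_partition)) {
    write_partition_tsv(sim$unpurified_partition,
                        file.path(dir, "unpurified_genome_totals.tsv"))
  }
  truth <- data.frame(
    gene_id = sim$truth$genes$gene_id,
    true_half_life_hours = sim$truth$genes$half_life,
    synthesis_rate = sim$truth$genes$synthesis,
    stringsAsFactors = FALSE
  )
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
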