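tp6 <- c(1, 2, 4, 8, 12, 24)

test_that("gene filter keeps >=1-in-all and >=5-in-one rows, including boundaries", {
  counts <- rbind(
    boundary_pass = c(1, 1, 1, 1, 1, 5),
    zero_point    = c(0, 9, 9, 9, 9, 9),
    never_five    = c(4, 4, 4, 4, 4, 4),
    strong        = c(10, 20, 30, 40, 50, 60)
  )
  am <- abundance_matrix(counts, tp6, "exon_count")
  kept <- filter_genes(am)
  expect_equal(rownames(kept$values), c("boundary_pass", "strong"))

  expect_error(filter_genes(abundance_matrix(
    rbind(g = rep(0, 6)), tp6, "exon_count")), "no genes pass")
})

test_that("intron filter keeps mean coverage >= 0.5, boundary inclusive", {
  cov <- rbind(boundary = rep(0.5, 6), zero = rep(0, 6),
               low = rep(0.49, 6), high = rep(3, 6))
  am <- abundance_matrix(cov, tp6, "intron_coverage")
  expect_equal(rownames(filter_introns(am)$values), c("boundary", "high"))
})

test_that("row filters match brute-force rule application on random tables", {
  set.seed(19)
  counts <- matrix(rpois(200 * 6, 3), 200, 6,
                   dimnames = list(sprintf("g%03d", 1:200), NULL))
  am <- abundance_matrix(counts, tp6, "exon_count")
  expected <- rownames(counts)[apply(counts, 1, function(x)
    all(x >= 1) && any(x >= 5))]
  expect_equal(rownames(filter_genes(am)$values), expected)

  cov <- matrix(round(rexp(150 * 6, 2), 3), 150, 6,
                dimnames = list(sprintf("i%03d", 1:150), NULL))
  amc <- abundance_matrix(cov, tp6, "intron_coverage")
  expected_i <- rownames(cov)[vapply(seq_len(nrow(cov)), function(i)
    mean(cov[i, ]) >= 0.5, logical(1))]
  expect_equal(rownames(filter_introns(amc)$values), expected_i)
})

test_that("clustering recovers the decreasing archetype as the selected set", {
  arch <- archetype_introns(n_each = 50, noise_sd = 0.05, seed = 7)
  rep <- cluster_and_select_introns(arch$matrix, k = 4, seed = 1)
  sel <- rep$selected_introns
  frac_decreasing <- mean(grepl("^decreasing", sel))
  expect_gte(sum(grepl("^decreasing", sel)) / 50, 0.95)
  expect_gte(frac_decreasing, 0.95)
})

test_that("a strictly decreasing centroid outscores a strictly increasing one", {
  cov <- rbind(matrix(rep(seq(2, 1, length.out = 6), each = 30), 30, 6,
                      byrow = FALSE),
               matrix(rep(seq(1, 2, length.out = 6), each = 30), 30, 6,
                      byrow = FALSE))
  cov <- cov + matrix(abs(rnorm(60 * 6, 0, 1e-3)), 60, 6)
  rownames(cov) <- sprintf("i%02d", 1:60)
  am <- abundance_matrix(cov, tp6, "intron_coverage")
  rep <- cluster_and_select_introns(am, k = 2, seed = 3)
  s <- rep$selection_scores
  dec <- rep$selected_cluster
  expect_lt(s$spearman_vs_time[s$cluster == dec],
            min(s$spearman_vs_time[s$cluster != dec]))
  # the selected cluster is the 30 decreasing introns
  expect_setequal(rep$selected_introns, sprintf("i%02d", 1:30))
})

test_that("a single shared decreasing profile yields one meaningful selected cluster", {
  prof <- 5 * exp(-0.2 * tp6)
  cov <- matrix(rep(prof, each = 3), 3, 6,
                dimnames = list(c("a", "b", "c"), NULL))
  am <- abundance_matrix(cov, tp6, "intron_coverage")
  expect_warning(rep <- cluster_and_select_introns(am, k = 4, seed = 1),
                 "distinct")
  expect_setequal(rep$selected_introns, c("a", "b", "c"))
})

test_that("cluster selection is deterministic and invariant to intron order", {
  arch <- archetype_introns(n_each = 25, seed = 13)
  r1 <- cluster_and_select_introns(arch$matrix, seed = 5)
  r2 <- cluster_and_select_introns(arch$matrix, seed = 5)
  expect_identical(r1$membership, r2$membership)

  perm <- sample(nrow(arch$matrix$values))
  shuffled <- abundance_matrix(arch$matrix$values[perm, ], tp6,
                               "intron_coverage")
  r3 <- cluster_and_select_introns(shuffled, seed = 5)
  expect_setequal(r3$selected_introns, r1$selected_introns)
})

test_that("manual cluster override bypasses the automatic choice", {
  arch <- archetype_introns(n_each = 25, seed = 13)
  r <- cluster_and_select_introns(arch$matrix, seed = 5)
  other <- setdiff(r$selection_scores$cluster, r$selected_cluster)[1]
  r2 <- cluster_and_select_introns(arch$matrix, seed = 5,
                                   select_cluster = other)
  expect_equal(r2$selected_cluster, other)
  expect_false(setequal(r2$selected_introns, r$selected_introns))
})

test_that("intron factors are the column sums of the selected set", {
  cov <- rbind(i1 = c(2, 1), i2 = c(4, 1))
  am <- abundance_matrix(cov, c(1, 4), "intron_coverage")
  expect_equal(unname(intron_normalization_factors(am, c("i1", "i2"))), c(6, 2))
  expect_equal(unname(intron_normalization_factors(am, "i2")), c(4, 1))
  expect_error(intron_normalization_factors(am, character(0)), "empty")
  expect_error(intron_normalization_factors(am, c("i1", "nope")), "absent")

  cov0 <- rbind(i1 = c(2, 0))
  am0 <- abundance_matrix(cov0, c(1, 4), "intron_coverage")
  expect_error(intron_normalization_factors(am0, "i1"), "time point")

  # oracle: column sums over a large random set
  set.seed(4)
  big <- matrix(rexp(1045 * 6), 1045, 6,
                dimnames = list(sprintf("i%04d", 1:1045), NULL))
  amb <- abundance_matrix(big, tp6, "intron_coverage")
  expect_equal(unname(intron_normalization_factors(amb, rownames(big))),
               unname(colSums(big)))
})

test_that("spike-in factors are the spike genome totals, failing when too sparse", {
  part <- genome_partition(rbind(human = c(8e5, 9e5), fly = c(2e5, 1e5)),
                           c(1, 24))
  expect_equal(unname(spikein_normalization_factors(part, "fly")), c(2e5, 1e5))
  expect_error(spikein_normalization_factors(part, "worm"), "label")

  sparse <- genome_partition(rbind(human = c(8e5, 9e5), fly = c(2e5, 400)),
                             c(1, 24))
  expect_error(spikein_normalization_factors(sparse, "fly"),
               "insufficient spike-in reads")
  expect_error(
    spikein_normalization_factors(
      genome_partition(rbind(fly = c(5, 0)), c(1, 24)), "fly", min_reads = 0),
    "insufficient")
})

test_that("normalization divides counts by factors elementwise", {
  am <- abundance_matrix(rbind(g1 = c(10, 20, 30)), c(1, 8, 24), "exon_count")
  ns <- normalize_abundance(am, c(10, 10, 10), mode = "none")
  expect_equal(unname(ns$values[1, ]), c(1, 2, 3))

  ns2 <- normalize_abundance(am, c(10, 20, 30), mode = "none")
  expect_equal(unname(ns2$values[1, ]), c(1, 1, 1))

  set.seed(8)
  m <- matrix(rpois(60, 20), 10, 6, dimnames = list(letters[1:10], NULL))
  f <- runif(6, 1, 5)
  am3 <- abundance_matrix(m, tp6, "exon_count")
  ns3 <- normalize_abundance(am3, f, "intron")
  expect_equal(ns3$values, sweep(m, 2, f, "/"), ignore_attr = TRUE)

  expect_error(normalize_abundance(am, c(1, 2), "none"), "shape")
  expect_error(normalize_abundance(am, c(1, 0, 2), "none"), "> 0")
})

test_that("normalized series are invariant to a common rescaling of a time point", {
  set.seed(9)
  m <- matrix(rpois(60, 50), 10, 6, dimnames = list(letters[1:10], NULL))
  f <- runif(6, 10, 20)
  base <- normalize_abundance(abundance_matrix(m, tp6, "exon_count"), f, "none")
  c_scale <- 7.3
  m2 <- m
  m2[, 3] <- m[, 3] * c_scale
  f2 <- f
  f2[3] <- f[3] * c_scale
  scaled <- normalize_abundance(abundance_matrix(m2, tp6, "exon_count"), f2,
                                "none")
  expect_equal(base$values, scaled$values)
})

test_that("enrichment QC returns the purified/unpurified ratio of ratios", {
  pur <- genome_partition(rbind(fly = c(1000, 800), yeast = c(100, 80)),
                          c(1, 24))
  unp <- genome_partition(rbind(fly = c(100, 100), yeast = c(1000, 1000)),
                          c(1, 24))
  expect_equal(unname(enrichment_qc(pur, unp, "fly", "yeast")), c(100, 100))
  expect_equal(unname(enrichment_qc(pur, pur, "fly", "yeast")), c(1, 1))

  zero <- genome_partition(rbind(fly = c(1, 1), yeast = c(0, 1)), c(1, 24))
  expect_error(enrichment_qc(zero, unp, "fly", "yeast"), "denominator")
})

test_that("simulated purification enrichment matches the configured carryover", {
  truth <- simulation_truth(n_genes = 200, n_introns = 100, carryover = 0.01,
                            seed = 3)
  sim <- simulate_labeling_experiment(truth, sampling = "multinomial")
  enr <- enrichment_qc(sim$partition, sim$unpurified_partition,
                       "spike_labeled", "spike_unlabeled")
  # sampling error aside, enrichment is 1/carryover = 100
  expect_true(all(enr > 60 & enr < 160))
})
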