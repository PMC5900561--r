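# Shared fixtures, built in code. Coordinates in exon/placement tables are
# 1-based closed (the GTF convention used by the data-frame inputs).

# Two genes on chr1: gA with two isoforms (tA1 three exons, tA2 two), gB
# single-exon. Longest transcript of gA is tA1 (300 nt vs 250 nt).
toy_exons <- function() {
  data.frame(
    chrom = "chr1",
    start = c(101, 301, 501, 101, 301, 1001),
    end   = c(200, 400, 600, 200, 350, 1100),
    strand = "+",
    gene_id = c("gA", "gA", "gA", "gA", "gA", "gB"),
    transcript_id = c("tA1", "tA1", "tA1", "tA2", "tA2", "tB1"),
    stringsAsFactors = FALSE
  )
}

# Deterministic placement table over the toy gene model.
toy_placements <- function(n = 20, seed = 42) {
  set.seed(seed)
  start <- sample(c(101:580, 1001:1080), n, replace = TRUE)
  data.frame(
    chrom = "chr1",
    start = start,
    end = start + 20,
    strand = sample(c("+", "-"), n, replace = TRUE),
    read_id = sprintf("r%02d", seq_len(n)),
    stringsAsFactors = FALSE
  )
}

# Brute-force per-read exon-overlap counter (union counting, the independent
# oracle for count_exon_reads). Exons given as a data frame.
oracle_exon_counts <- function(placements, exons, gene_strand,
                               strandedness = "unstranded") {
  genes <- unique(exons$gene_id)
  counts <- stats::setNames(numeric(length(genes)), genes)
  for (rid in unique(placements$read_id)) {
    blocks <- placements[placements$read_id == rid, ]
    hit_genes <- character(0)
    for (b in seq_len(nrow(blocks))) {
      for (e in seq_len(nrow(exons))) {
        if (blocks$chrom[b] != exons$chrom[e]) next
        if (blocks$start[b] > exons$end[e] || blocks$end[b] < exons$start[e]) next
        g <- exons$gene_id[e]
        ok <- switch(strandedness,
                     unstranded = TRUE,
                     forward = blocks$strand[b] == gene_strand[g],
                     reverse = blocks$strand[b] != gene_strand[g])
        if (ok) hit_genes <- union(hit_genes, g)
      }
    }
    if (length(hit_genes) == 1) counts[hit_genes] <- counts[hit_genes] + 1
  }
  counts
}

# Brute-force per-base depth accumulator over one interval (1-based closed).
oracle_mean_coverage <- function(placements, start, end) {
  depth <- numeric(end - start + 1)
  for (i in seq_len(nrow(placements))) {
    lo <- max(placements$start[i], start)
    hi <- min(placements$end[i], end)
    if (lo <= hi) {
      idx <- (lo - start + 1):(hi - start + 1)
      depth[idx] <- depth[idx] + 1
    }
  }
  mean(depth)
}

# A small noiseless normalized series for fit tests.
bounded_series <- function(n0, lam, gamma = 0, t = c(1, 2, 4, 8, 12, 24)) {
  list(t = t, y = n0 * (1 - exp(-(lam + gamma) * t)))
}

# Intron coverage matrix with four archetypal time profiles (decreasing,
# flat, increasing, hump), n of each, seeded multiplicative noise.
archetype_introns <- function(n_each = 50, noise_sd = 0.05, seed = 7,
                              time_points = c(1, 2, 4, 8, 12, 24)) {
  set.seed(seed)
  k <- length(time_points)
  shapes <- list(
    decreasing = seq(1.6, 0.4, length.out = k),
    flat = rep(1, k),
    increasing = seq(0.4, 1.6, length.out = k),
    hump = 1 + 0.8 * sin(seq(0, pi, length.out = k))
  )
  rows <- list()
  labels <- character(0)
  for (nm in names(shapes)) {
    mag <- exp(stats::runif(n_each, log(1), log(20)))
    noise <- matrix(stats::rnorm(n_each * k, 0, noise_sd), n_each, k)
    rows[[nm]] <- mag * matrix(rep(shapes[[nm]], each = n_each), n_each, k) *
      exp(noise)
    labels <- c(labels, rep(nm, n_each))
  }
  m <- do.call(rbind, rows)
  rownames(m) <- sprintf("%s_%03d", labels, seq_len(nrow(m)))
  list(matrix = abundance_matrix(m, time_points, "intron_coverage"),
       archetype = stats::setNames(labels, rownames(m)))
}

# Spearman of converged half-lives against the simulation truth.
truth_spearman <- function(run, truth) {
  hl <- run$half_lives
  m <- merge(hl[hl$converged, c("gene_id", "half_life")], truth$genes,
             by = "gene_id")
  stats::cor(m$half_life.x, m$half_life.y, method = "spearman")
}
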