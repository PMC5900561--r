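model_toy <- filter_introns_by_exon_overlap(
  select_longest_transcript(toy_exons()),
  toy_exons()[toy_exons()$transcript_id == "tA1" |
                toy_exons()$gene_id == "gB", ])

test_that("a read inside a single exon increments exactly that gene", {
  p <- data.frame(chrom = "chr1", start = 120, end = 160, strand = "+",
                  stringsAsFactors = FALSE)
  res <- count_exon_reads(p, model_toy, strandedness = "unstranded")
  expect_equal(res$counts[["gA"]], 1)
  expect_equal(res$counts[["gB"]], 0)
  expect_equal(res$n_ambiguous, 0)
})

test_that("reads touching exons of two genes are discarded as ambiguous", {
  genes2 <- data.frame(chrom = "chr3", start = c(1, 81), end = c(100, 180),
                       strand = "+", gene_id = c("gX", "gY"),
                       transcript_id = c("tX", "tY"), stringsAsFactors = FALSE)
  m2 <- select_longest_transcript(genes2)
  p <- data.frame(chrom = "chr3", start = 90, end = 110, strand = "+",
                  stringsAsFactors = FALSE)
  res <- count_exon_reads(p, m2, strandedness = "unstranded")
  expect_equal(unname(res$counts), c(0, 0))
  expect_equal(res$n_ambiguous, 1)
})

test_that("reads on chromosomes absent from the model land in the unassigned bucket", {
  p <- data.frame(chrom = c("chr1", "chrUn"), start = c(120, 5),
                  end = c(160, 55), strand = "+", stringsAsFactors = FALSE)
  res <- count_exon_reads(p, model_toy, strandedness = "unstranded")
  expect_equal(res$n_unassigned, 1)
  expect_equal(sum(res$counts), 1)
})

test_that("reverse strandedness counts antisense reads and forward counts sense reads", {
  p_sense <- data.frame(chrom = "chr1", start = 120, end = 160, strand = "+",
                        stringsAsFactors = FALSE)
  p_anti <- p_sense
  p_anti$strand <- "-"
  expect_equal(count_exon_reads(p_sense, model_toy, "forward")$counts[["gA"]], 1)
  expect_equal(count_exon_reads(p_sense, model_toy, "reverse")$counts[["gA"]], 0)
  expect_equal(count_exon_reads(p_anti, model_toy, "reverse")$counts[["gA"]], 1)
})

test_that("union counting matches the brute-force oracle on a 20-read toy set", {
  p <- toy_placements(20)
  exons_chosen <- toy_exons()[toy_exons()$transcript_id %in% c("tA1", "tB1"), ]
  gene_strand <- c(gA = "+", gB = "+")
  for (s in c("unstranded", "forward", "reverse")) {
    res <- count_exon_reads(p, model_toy, s)
    expect_equal(res$counts, oracle_exon_counts(p, exons_chosen, gene_strand, s))
    expect_lte(sum(res$counts), nrow(p))
  }
})

test_that("a 50-base read inside a 100-base intron gives mean coverage 0.5", {
  # gA intron 1 spans 201-300 (100 nt)
  p <- data.frame(chrom = "chr1", start = 221, end = 270, strand = "+",
                  stringsAsFactors = FALSE)
  cov <- intron_mean_coverage(p, model_toy)
  expect_equal(cov[["gA|1"]], 0.5)
  expect_equal(cov[["gA|2"]], 0)
})

test_that("mean coverage equals brute-force per-base accumulation for staggered reads", {
  # a 200-base test intron: gene with exons 1-100 and 301-400 on chr4
  ex <- data.frame(chrom = "chr4", start = c(1, 301), end = c(100, 400),
                   strand = "+", gene_id = "gC", transcript_id = "tC",
                   stringsAsFactors = FALSE)
  m <- select_longest_transcript(ex)
  p <- data.frame(chrom = "chr4", start = c(90, 150, 260), end = c(170, 240, 340),
                  strand = "+", read_id = c("r1", "r2", "r3"),
                  stringsAsFactors = FALSE)
  cov <- intron_mean_coverage(p, m)
  expect_equal(cov[["gC|1"]], oracle_mean_coverage(p, 101, 300))

  # reads outside the intron -> 0
  empty <- intron_mean_coverage(
    data.frame(chrom = "chr4", start = 1, end = 50, strand = "+"), m)
  expect_equal(unname(empty), 0)
})

test_that("spliced blocks are treated independently: junction reads add no intron coverage", {
  ex <- data.frame(chrom = "chr4", start = c(1, 301), end = c(100, 400),
                   strand = "+", gene_id = "gC", transcript_id = "tC",
                   stringsAsFactors = FALSE)
  m <- select_longest_transcript(ex)
  junction <- data.frame(chrom = "chr4", start = c(81, 301), end = c(100, 330),
                         strand = "+", read_id = c("j", "j"),
                         stringsAsFactors = FALSE)
  expect_equal(unname(intron_mean_coverage(junction, m)), 0)
  res <- count_exon_reads(junction, m, "unstranded")
  expect_equal(res$counts[["gC"]], 1)  # two blocks, one read, one count
})

test_that("intron coverage is exactly linear in read depth", {
  p <- toy_placements(30, seed = 5)
  cov1 <- intron_mean_coverage(p, model_toy)
  p2 <- rbind(p, transform(p, read_id = paste0(read_id, "b")))
  expect_equal(intron_mean_coverage(p2, model_toy), 2 * cov1)
})

test_that("per-genome partitioning tallies reads by chromosome label", {
  map <- c(hg38_chr1 = "human", dm6_chr2L = "fly", sc3_chrI = "yeast")
  p <- data.frame(
    chrom = c(rep("hg38_chr1", 5), rep("dm6_chr2L", 3), rep("sc3_chrI", 2),
              "weird_chr"),
    start = 1, end = 50, strand = "+", stringsAsFactors = FALSE)
  tot <- partition_by_genome(p, map)
  expect_equal(tot[["human"]], 5)
  expect_equal(tot[["fly"]], 3)
  expect_equal(tot[["yeast"]], 2)
  expect_equal(tot[["unassigned"]], 1)
  expect_equal(sum(tot), nrow(p))

  none <- partition_by_genome(p[0, ], map)
  expect_true(all(none == 0))
})

test_that("quantify_time_course assembles matrices aligned with the time points", {
  tp <- c(1, 4, 24)
  placements <- lapply(c(3, 6, 9), toy_placements, n = 40)
  q <- quantify_time_course(placements, tp, model_toy,
                            strandedness = "unstranded",
                            genome_label_map = c(chr1 = "target"))
  expect_s3_class(q$exon_counts, "abundance_matrix")
  expect_equal(q$exon_counts$time_points, tp)
  expect_equal(nrow(q$intron_coverage$values), 2)
  expect_equal(rownames(q$partition$values), c("target", "unassigned"))
})
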