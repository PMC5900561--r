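test_that("the longest transcript is chosen per gene and introns are the exon gaps", {
  model <- select_longest_transcript(toy_exons())
  expect_equal(sort(model$genes$gene_id), c("gA", "gB"))
  # tA1 (300 exonic nt) beats tA2 (250 nt)
  expect_equal(model$genes$transcript_id[model$genes$gene_id == "gA"], "tA1")

  intr <- model$introns
  ga <- intr[intr$gene_id == "gA"]
  expect_equal(GenomicRanges::start(ga), c(201, 401))
  expect_equal(GenomicRanges::end(ga), c(300, 500))
  # single-exon gene: no introns
  expect_equal(sum(intr$gene_id == "gB"), 0)
})

test_that("equal-length transcripts tie-break to the smallest transcript id", {
  ex <- data.frame(chrom = "chr1", start = c(1, 1), end = c(100, 100),
                   strand = "+", gene_id = "g1",
                   transcript_id = c("tZ", "tA"), stringsAsFactors = FALSE)
  model <- select_longest_transcript(ex)
  expect_equal(model$genes$transcript_id, "tA")
})

test_that("malformed exon records are rejected with the record identified", {
  ex <- toy_exons()
  ex$end[3] <- ex$start[3] - 5
  expect_error(select_longest_transcript(ex), "row 3")

  tx <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 500), strand = "+")
  tx$transcript_id <- "tA1"
  expect_error(select_longest_transcript(toy_exons(), transcripts = tx),
               "outside its transcript")
})

test_that("introns sharing any base with an isoform exon are removed, abutting ones kept", {
  model <- select_longest_transcript(toy_exons())
  # gA intron 1 is 201-300; an exon 251-350 overlaps it, an exon 301-400 abuts
  overlapping <- data.frame(chrom = "chr1", start = 251, end = 350,
                            strand = "+", gene_id = "gX",
                            stringsAsFactors = FALSE)
  abutting <- data.frame(chrom = "chr1", start = 301, end = 400, strand = "+",
                         gene_id = "gX", stringsAsFactors = FALSE)
  m1 <- filter_introns_by_exon_overlap(model, overlapping)
  expect_equal(GenomicRanges::start(m1$introns), 401)
  m2 <- filter_introns_by_exon_overlap(model, abutting)
  expect_equal(length(m2$introns), 2)

  # empty exon set is a no-op
  m3 <- filter_introns_by_exon_overlap(model, GenomicRanges::GRanges())
  expect_equal(length(m3$introns), 2)
})

test_that("overlap filtering is strand-agnostic by default and gene-scoped on request", {
  model <- select_longest_transcript(toy_exons())
  minus_exon <- data.frame(chrom = "chr1", start = 251, end = 350,
                           strand = "-", gene_id = "gOther",
                           stringsAsFactors = FALSE)
  m <- filter_introns_by_exon_overlap(model, minus_exon)
  expect_equal(length(m$introns), 1)
  m_same <- filter_introns_by_exon_overlap(model, minus_exon, scope = "same_gene")
  expect_equal(length(m_same$introns), 2)
})

test_that("a 5-intron toy set with 2 overlapped exons retains 3 introns", {
  ex <- data.frame(
    chrom = "chr2",
    start = c(1, 201, 401, 601, 801, 1001),
    end   = c(100, 300, 500, 700, 900, 1100),
    strand = "+", gene_id = "gM", transcript_id = "tM",
    stringsAsFactors = FALSE)
  model <- select_longest_transcript(ex)
  expect_equal(length(model$introns), 5)
  iso <- data.frame(chrom = "chr2", start = c(120, 750), end = c(150, 790),
                    strand = "+", gene_id = "gM", stringsAsFactors = FALSE)
  filtered <- filter_introns_by_exon_overlap(model, iso)
  expect_equal(length(filtered$introns), 3)

  # idempotence: filtering the filtered model again changes nothing
  again <- filter_introns_by_exon_overlap(filtered, iso)
  expect_identical(as.data.frame(again$introns), as.data.frame(filtered$introns))
})

test_that("retained introns abut chosen exons and match a brute-force overlap check", {
  set.seed(31)
  for (rep in 1:5) {
    # random multi-gene annotation on one chromosome
    n_genes <- 8
    exons <- do.call(rbind, lapply(seq_len(n_genes), function(g) {
      n_ex <- sample(1:5, 1)
      starts <- sort(sample(seq(1, 20000, by = 10), n_ex))
      widths <- sample(50:200, n_ex, replace = TRUE)
      data.frame(chrom = "chrS", start = starts, end = starts + widths,
                 strand = sample(c("+", "-"), 1),
                 gene_id = sprintf("g%02d", g),
                 transcript_id = sprintf("t%02d", g),
                 stringsAsFactors = FALSE)
    }))
    # drop genes whose exons accidentally overlap within the transcript
    model <- select_longest_transcript(exons)
    filtered <- filter_introns_by_exon_overlap(model, exons)

    # conservation: each intron lies inside its gene's span, abutting exons
    for (i in seq_along(filtered$introns)) {
      intr <- filtered$introns[i]
      g <- intr$gene_id
      gex <- model$exons[model$exons$gene_id == g]
      expect_true(GenomicRanges::start(intr) > min(GenomicRanges::start(gex)))
      expect_true(GenomicRanges::end(intr) < max(GenomicRanges::end(gex)))
      expect_true((GenomicRanges::start(intr) - 1) %in% GenomicRanges::end(gex))
      expect_true((GenomicRanges::end(intr) + 1) %in% GenomicRanges::start(gex))
    }

    # equivalence with an all-pairs interval intersection
    all_intr <- select_longest_transcript(exons)$introns
    keep <- vapply(seq_along(all_intr), function(i) {
      s <- GenomicRanges::start(all_intr)[i]
      e <- GenomicRanges::end(all_intr)[i]
      !any(exons$start <= e & exons$end >= s)
    }, logical(1))
    expect_equal(length(filtered$introns), sum(keep))
  }
})

test_that("feature models round-trip through BED output", {
  model <- filter_introns_by_exon_overlap(select_longest_transcript(toy_exons()),
                                          toy_exons())
  dir <- withr::local_tempdir()
  write_feature_model_bed(model, dir)
  exons_bed <- rtracklayer::import(file.path(dir, "exons.bed"))
  expect_equal(length(exons_bed), length(model$exons))
  expect_equal(GenomicRanges::start(exons_bed), GenomicRanges::start(model$exons))
  expect_true(all(grepl("^g[AB]\\|\\d+$", exons_bed$name)))
})
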