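# Coerce read placements to a GRanges of aligned blocks with a read_id
# metadata column. A data frame uses 1-based closed coordinates and columns
# chrom/start/end/strand (+ optional read_id when a spliced read contributes
# several blocks). Without read_id every row is its own read.
as_placements <- function(x) {
  if (is.data.frame(x)) {
    need <- c("chrom", "start", "end", "strand")
    missing <- setdiff(need, names(x))
    if (length(missing) > 0) {
      stop("placement table lacks columns: ", paste(missing, collapse = ", "))
    }
    gr <- GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start, x$end),
                                 strand = x$strand)
    gr$read_id <- if ("read_id" %in% names(x)) as.character(x$read_id) else
      as.character(seq_len(nrow(x)))
    return(gr)
  }
  if (!methods::is(x, "GRanges")) {
    stop("expected placements as a GRanges or data frame")
  }
  if (!"read_id" %in% names(S4Vectors::mcols(x))) {
    x$read_id <- as.character(seq_along(x))
  }
  x
}

#' Read placements from a TSV table
#'
#' Columns `chrom`, `start`, `end`, `strand` (1-based closed coordinates) and
#' optionally `read_id` (shared by the blocks of a spliced read).
#'
#' @param path TSV path.
#' @return GRanges of aligned blocks with a `read_id` column.
#' @export
read_placements_tsv <- function(path) {
  as_placements(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Read placements from a BAM file
#'
#' Each alignment's aligned blocks (CIGAR M/=/X segments) become separate
#' ranges sharing a `read_id`, so junction reads never contribute coverage to
#' the intron they span.
#'
#' @param path coordinate-sorted, indexed BAM.
#' @return GRanges of aligned blocks with a `read_id` column.
#' @export
read_placements_bam <- function(path) {
  if (!requireNamespace("GenomicAlignments", quietly = TRUE)) {
    stop("reading BAM requires the GenomicAlignments package")
  }
  ga <- GenomicAlignments::readGAlignments(path)
  blocks <- GenomicAlignments::grglist(ga)
  gr <- unlist(blocks, use.names = FALSE)
  gr$read_id <- rep(as.character(seq_along(blocks)),
                    S4Vectors::elementNROWS(blocks))
  gr
}

# TRUE where a block's strand is compatible with its gene's strand under the
# library chemistry. "*" on either side matches anything.
strand_compatible <- function(read_strand, gene_strand, strandedness) {
  if (strandedness == "unstranded") return(rep(TRUE, length(read_strand)))
  wild <- read_strand == "*" | gene_strand == "*"
  if (strandedness == "forward") {
    wild | read_strand == gene_strand
  } else {
    wild | read_strand != gene_strand
  }
}

#' Count reads over the exons of the chosen transcripts
#'
#' Union counting: a read increments a gene when at least one of its aligned
#' blocks overlaps an exon of that gene's chosen transcript and no other
#' gene's exons; reads compatible with two or more genes are discarded as
#' ambiguous. Reads whose blocks all fall on chromosomes absent from the
#' feature model are tallied in an `unassigned` bucket rather than silently
#' dropped. Strandedness defaults to `"reverse"` (dUTP/TruSeq stranded
#' chemistry: reads map antisense to the transcript).
#'
#' @param placements read placements (GRanges of blocks with `read_id`, a
#'   placement data frame, or a TSV/BAM loaded with the readers).
#' @param model a `feature_model`.
#' @param strandedness `"reverse"`, `"forward"` or `"unstranded"`.
#' @return List: `counts` (named vector over the model's genes),
#'   `n_ambiguous`, `n_unassigned`, `n_reads`.
#' @export
count_exon_reads <- function(placements, model,
                             strandedness = c("reverse", "forward", "unstranded")) {
  strandedness <- match.arg(strandedness)
  stopifnot(inherits(model, "feature_model"))
  p <- as_placements(placements)
  ex <- model$exons

  model_chroms <- unique(c(as.character(GenomicRanges::seqnames(ex)),
                           as.character(GenomicRanges::seqnames(model$introns))))
  on_known <- as.character(GenomicRanges::seqnames(p)) %in% model_chroms
  read_known <- tapply(on_known, p$read_id, any)
  n_unassigned <- sum(!read_known)

  hits <- GenomicRanges::findOverlaps(p, ex, ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  ok <- strand_compatible(as.character(GenomicRanges::strand(p))[q],
                          as.character(GenomicRanges::strand(ex))[s],
                          strandedness)
  pairs <- unique(data.frame(read_id = p$read_id[q][ok],
                             gene_id = ex$gene_id[s][ok],
                             stringsAsFactors = FALSE))
  genes_per_read <- table(pairs$read_id)
  unambiguous <- names(genes_per_read)[genes_per_read == 1]
  n_ambiguous <- sum(genes_per_read > 1)

  counts <- stats::setNames(numeric(nrow(model$genes)), model$genes$gene_id)
  if (length(unambiguous) > 0) {
    tab <- table(pairs$gene_id[pairs$read_id %in% unambiguous])
    counts[names(tab)] <- as.numeric(tab)
  }
  list(counts = counts, n_ambiguous = n_ambiguous,
       n_unassigned = n_unassigned, n_reads = length(unique(p$read_id)))
}

#' Mean per-base coverage over the retained introns
#'
#' Per-base depth is accumulated over each intron from the aligned blocks
#' (reads need not be intron-exclusive; spliced blocks contribute only where
#' they align) and averaged over the intron length, giving finer quantitation
#' than a read count. Coverage is computed strand-agnostically.
#'
#' @inheritParams count_exon_reads
#' @return Named numeric vector of mean coverages over the model's introns.
#' @export
intron_mean_coverage <- function(placements, model) {
  stopifnot(inherits(model, "feature_model"))
  p <- as_placements(placements)
  intr <- model$introns
  ids <- paste0(intr$gene_id, "|", intr$feature_rank)
  out <- stats::setNames(numeric(length(intr)), ids)
  if (length(intr) == 0 || length(p) == 0) return(out)
  cov <- GenomicRanges::coverage(p)
  chroms <- as.character(GenomicRanges::seqnames(intr))
  for (chr in unique(chroms)) {
    if (!chr %in% names(cov)) next
    rle <- cov[[chr]]
    sel <- which(chroms == chr)
    r <- IRanges::ranges(intr[sel])
    need <- max(IRanges::end(r)) - length(rle)
    if (need > 0) rle <- c(rle, S4Vectors::Rle(0L, need))
    v <- IRanges::Views(rle, r)
    out[sel] <- sum(v) / GenomicRanges::width(intr[sel])
  }
  out
}

#' Tally reads per source genome
#'
#' For merged multi-genome references every chromosome belongs to exactly one
#' source genome; reads are tallied per genome label, with unknown
#' chromosomes collected under `unassigned`.
#'
#' @param placements read placements (see [count_exon_reads()]).
#' @param genome_label_map named character vector, chromosome -> genome label.
#' @return Named numeric vector of read totals: one entry per label in the
#'   map, plus `unassigned`.
#' @export
partition_by_genome <- function(placements, genome_label_map) {
  if (is.null(names(genome_label_map)) || any(names(genome_label_map) == "")) {
    stop("genome_label_map must be a named vector (chromosome -> label)")
  }
  p <- as_placements(placements)
  first <- !duplicated(p$read_id)
  chrom <- as.character(GenomicRanges::seqnames(p))[first]
  label <- genome_label_map[chrom]
  label[is.na(label)] <- "unassigned"
  out <- stats::setNames(numeric(length(unique(genome_label_map)) + 1),
                         c(unique(genome_label_map), "unassigned"))
  tab <- table(label)
  out[names(tab)] <- as.numeric(tab)
  out
}

#' Quantify a whole time course
#'
#' Runs [count_exon_reads()], [intron_mean_coverage()] and (when a genome
#' label map is given) [partition_by_genome()] for each time point and
#' assembles the abundance matrices.
#'
#' @param placements_by_time list of placements, one per time point, in time
#'   order.
#' @param time_points sampling times in hours.
#' @param model a `feature_model`.
#' @param strandedness counting strandedness, see [count_exon_reads()].
#' @param genome_label_map optional chromosome -> genome label map.
#' @return List: `exon_counts`, `intron_coverage` ([abundance_matrix()]s),
#'   `partition` (a [genome_partition()] or NULL), `unassigned` (per time
#'   point).
#' @export
quantify_time_course <- function(placements_by_time, time_points, model,
                                 strandedness = "reverse",
                                 genome_label_map = NULL) {
  stopifnot(length(placements_by_time) == length(time_points))
  cols <- lapply(placements_by_time, count_exon_reads, model = model,
                 strandedness = strandedness)
  exon <- abundance_matrix(do.call(cbind, lapply(cols, `[[`, "counts")),
                           time_points, "exon_count")
  icov <- do.call(cbind, lapply(placements_by_time, intron_mean_coverage,
                                model = model))
  intron <- if (nrow(icov) > 0) {
    abundance_matrix(icov, time_points, "intron_coverage")
  } else NULL
  part <- NULL
  if (!is.null(genome_label_map)) {
    pm <- do.call(cbind, lapply(placements_by_time, partition_by_genome,
                                genome_label_map = genome_label_map))
    part <- genome_partition(pm, time_points)
  }
  list(exon_counts = exon, intron_coverage = intron, partition = part,
       unassigned = vapply(cols, `[[`, numeric(1), "n_unassigned"))
}
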