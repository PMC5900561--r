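#' @import methods
#' @importFrom GenomicRanges GRanges findOverlaps reduce psetdiff seqnames
#'   strand width start end coverage
#' @importFrom IRanges IRanges ranges Views
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits elementNROWS
NULL

# Coerce exon records to a GRanges with gene_id / transcript_id metadata.
# Data-frame input uses 1-based closed coordinates (the GTF convention).
as_exon_granges <- function(x, require_tx = TRUE) {
  if (is.data.frame(x)) {
    need <- c("chrom", "start", "end", "strand", "gene_id")
    if (require_tx) need <- c(need, "transcript_id")
    missing <- setdiff(need, names(x))
    if (length(missing) > 0) {
      stop("exon table lacks columns: ", paste(missing, collapse = ", "))
    }
    bad <- which(x$end < x$start)
    if (length(bad) > 0) {
      stop("malformed exon record (end < start) at row ", bad[1], ": ",
           paste(x[bad[1], need[1:4]], collapse = " "))
    }
    gr <- GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start, x$end),
                                 strand = x$strand)
    gr$gene_id <- x$gene_id
    if ("transcript_id" %in% names(x)) gr$transcript_id <- x$transcript_id
    return(gr)
  }
  if (!methods::is(x, "GRanges")) stop("expected a GRanges or a data frame of exons")
  need <- c("gene_id", if (require_tx) "transcript_id")
  missing <- setdiff(need, names(S4Vectors::mcols(x)))
  if (length(missing) > 0) {
    stop("exon GRanges lacks metadata columns: ", paste(missing, collapse = ", "))
  }
  bad <- which(!as.character(GenomicRanges::strand(x)) %in% c("+", "-"))
  if (length(bad) > 0) {
    stop("exon record ", bad[1], " has no usable strand")
  }
  x
}

#' Read exon records from a GTF/GFF annotation
#'
#' Imports the annotation with rtracklayer and returns the exon features with
#' their `gene_id` and `transcript_id` attributes (Ensembl and UCSC GTF
#' dialects).
#'
#' @param path GTF or GFF file.
#' @return GRanges of exons with `gene_id` and `transcript_id` metadata.
#' @export
read_annotation_exons <- function(path) {
  gr <- rtracklayer::import(path)
  if (!"type" %in% names(S4Vectors::mcols(gr))) stop("no feature type column in ", path)
  ex <- gr[gr$type == "exon"]
  if (length(ex) == 0) stop("no exon records in ", path)
  as_exon_granges(ex)
}

#' Select one representative (longest) transcript per gene
#'
#' For every gene, picks the transcript whose summed exon length is maximal
#' (ties broken by the lexicographically smallest transcript id), merges and
#' sorts its exons, and derives introns as the gaps between consecutive
#' exons. Single-exon genes yield an empty intron list. The returned feature
#' model still carries all introns; run [filter_introns_by_exon_overlap()]
#' before quantification.
#'
#' @param exons exon records: a GRanges (or data frame with 1-based closed
#'   `chrom`, `start`, `end`, `strand` columns) carrying `gene_id` and
#'   `transcript_id`.
#' @param transcripts optional GRanges of transcript spans with
#'   `transcript_id` metadata; when supplied, exons falling outside their
#'   transcript are rejected.
#' @param genome_label_map optional named character vector mapping chromosome
#'   names to source-genome labels (multi-genome references); unmapped
#'   chromosomes get label `"genome"`.
#' @return An object of class `feature_model`: `genes` data frame (`gene_id`,
#'   `transcript_id`, `genome_label`), `exons` and `introns` GRanges with
#'   `gene_id` and `feature_rank` metadata, and an `intron_filtered` flag.
#' @export
select_longest_transcript <- function(exons, transcripts = NULL,
                                      genome_label_map = NULL) {
  ex <- as_exon_granges(exons)
  if (length(ex) == 0) stop("no exon records supplied")

  if (!is.null(transcripts)) {
    if (!"transcript_id" %in% names(S4Vectors::mcols(transcripts))) {
      stop("transcripts GRanges lacks transcript_id")
    }
    idx <- match(ex$transcript_id, transcripts$transcript_id)
    known <- !is.na(idx)
    outside <- known & !(
      as.character(GenomicRanges::seqnames(ex)) ==
        as.character(GenomicRanges::seqnames(transcripts))[idx] &
      GenomicRanges::start(ex) >= GenomicRanges::start(transcripts)[idx] &
      GenomicRanges::end(ex) <= GenomicRanges::end(transcripts)[idx])
    if (any(outside)) {
      o <- which(outside)[1]
      stop("exon outside its transcript: ", ex$transcript_id[o], " at ",
           as.character(GenomicRanges::seqnames(ex))[o], ":",
           GenomicRanges::start(ex)[o], "-", GenomicRanges::end(ex)[o])
    }
  }

  tx <- unique(data.frame(gene_id = ex$gene_id,
                          transcript_id = ex$transcript_id,
                          stringsAsFactors = FALSE))
  exlen <- tapply(GenomicRanges::width(ex), ex$transcript_id, sum)
  tx$exonic_length <- as.numeric(exlen[tx$transcript_id])
  # longest transcript per gene; ties to the lexicographically smallest id
  tx <- tx[order(tx$gene_id, -tx$exonic_length, tx$transcript_id), ]
  chosen <- tx[!duplicated(tx$gene_id), c("gene_id", "transcript_id")]

  ex_ch <- ex[ex$transcript_id %in% chosen$transcript_id]
  exl <- GenomicRanges::reduce(
    GenomicRanges::split(ex_ch, factor(ex_ch$gene_id, levels = chosen$gene_id)))
  rngl <- range(exl)
  if (any(S4Vectors::elementNROWS(rngl) != 1)) {
    bad <- names(rngl)[S4Vectors::elementNROWS(rngl) != 1][1]
    stop("chosen transcript of gene ", bad, " spans multiple chromosomes/strands")
  }
  intl <- GenomicRanges::psetdiff(unlist(rngl), exl)

  flatten <- function(grl) {
    gr <- unlist(grl, use.names = FALSE)
    gr$gene_id <- rep(names(grl), S4Vectors::elementNROWS(grl))
    ranks <- unlist(lapply(S4Vectors::elementNROWS(grl), seq_len), use.names = FALSE)
    gr$feature_rank <- if (length(gr) > 0) ranks else integer(0)
    gr
  }
  chrom_of_gene <- as.character(GenomicRanges::seqnames(unlist(rngl)))
  label <- rep("genome", nrow(chosen))
  if (!is.null(genome_label_map)) {
    hit <- chrom_of_gene %in% names(genome_label_map)
    label[hit] <- genome_label_map[chrom_of_gene[hit]]
  }
  genes <- data.frame(chosen, genome_label = label, stringsAsFactors = FALSE,
                      row.names = NULL)

  structure(list(genes = genes, exons = flatten(exl), introns = flatten(intl),
                 intron_filtered = FALSE),
            class = "feature_model")
}

#' @export
print.feature_model <- function(x, ...) {
  cat(sprintf(
    "feature_model: %d genes, %d exons, %d introns (%sfiltered)\n",
    nrow(x$genes), length(x$exons), length(x$introns),
    if (x$intron_filtered) "" else "not "))
  invisible(x)
}

#' Remove introns that overlap any isoform exon
#'
#' Reads from mature mRNA of an overlapping exon would contaminate the intron
#' signal, so every intron of the feature model that shares at least one base
#' with any exon in `all_isoform_exons` is dropped. The comparison is
#' strand-agnostic. By default exons of any gene disqualify an intron
#' (`scope = "all_genes"`); `scope = "same_gene"` restricts the check to
#' other isoforms of the intron's own gene.
#'
#' @param model a `feature_model` from [select_longest_transcript()].
#' @param all_isoform_exons GRanges (or exon data frame) covering every
#'   isoform of every gene; an empty set is a valid no-op.
#' @param scope `"all_genes"` or `"same_gene"`.
#' @return The `feature_model` with overlapped introns removed and
#'   `intron_filtered = TRUE`.
#' @export
filter_introns_by_exon_overlap <- function(model, all_isoform_exons,
                                           scope = c("all_genes", "same_gene")) {
  stopifnot(inherits(model, "feature_model"))
  scope <- match.arg(scope)
  ex <- if (is.data.frame(all_isoform_exons) || length(all_isoform_exons) > 0) {
    as_exon_granges(all_isoform_exons, require_tx = FALSE)
  } else {
    all_isoform_exons
  }
  if (length(model$introns) > 0 && length(ex) > 0) {
    hits <- GenomicRanges::findOverlaps(model$introns, ex, ignore.strand = TRUE)
    if (scope == "same_gene") {
      same <- model$introns$gene_id[S4Vectors::queryHits(hits)] ==
        ex$gene_id[S4Vectors::subjectHits(hits)]
      hits <- hits[same]
    }
    drop <- unique(S4Vectors::queryHits(hits))
    if (length(drop) > 0) model$introns <- model$introns[-drop]
  }
  model$intron_filtered <- TRUE
  model
}

#' Write a feature model as BED6 files
#'
#' Writes `exons.bed` and `introns.bed` (0-based half-open BED convention)
#' into `dir`, with `name = gene_id|feature_rank`.
#'
#' @param model a `feature_model`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_feature_model_bed <- function(model, dir) {
  stopifnot(inherits(model, "feature_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  as_bed <- function(gr) {
    if (length(gr) > 0) {
      gr$name <- paste0(gr$gene_id, "|", gr$feature_rank)
      gr$score <- 0
    }
    gr
  }
  rtracklayer::export(as_bed(model$exons), file.path(dir, "exons.bed"),
                      format = "BED")
  rtracklayer::export(as_bed(model$introns), file.path(dir, "introns.bed"),
                      format = "BED")
  invisible(dir)
}

#' Build a filtered feature model from a GTF annotation
#'
#' Convenience wrapper: read exons, select the longest transcript per gene,
#' and purge introns overlapping any isoform exon.
#'
#' @param annotation GTF/GFF path, or an exon GRanges/data frame.
#' @param scope overlap scope passed to [filter_introns_by_exon_overlap()].
#' @param genome_label_map passed to [select_longest_transcript()].
#' @return A filtered `feature_model`.
#' @export
build_feature_model <- function(annotation, scope = "all_genes",
                                genome_label_map = NULL) {
  ex <- if (is.character(annotation) && length(annotation) == 1) {
    read_annotation_exons(annotation)
  } else {
    as_exon_granges(annotation)
  }
  model <- select_longest_transcript(ex, genome_label_map = genome_label_map)
  filter_introns_by_exon_overlap(model, ex, scope = scope)
}
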