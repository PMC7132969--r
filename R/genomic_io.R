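# Readers/writers for the standard formats the pipeline touches, plus the
# gene-model container shared by every downstream stage.

#' Gene model: exons plus transcript structures of one gene
#'
#' A light S3 container for a single gene: a sorted, pairwise-disjoint set of
#' exon intervals and named transcripts given as strictly increasing indices
#' into that exon set. Introns are derivable as the gaps between consecutive
#' exons.
#'
#' @param gene_id gene identifier
#' @param chrom chromosome name
#' @param strand "+", "-" or "*" (unknown)
#' @param exons a [GenomicRanges::GRanges] or data.frame with `start`/`end`
#'   (1-based inclusive); must be pairwise disjoint
#' @param transcripts named list of strictly increasing integer vectors
#'   indexing `exons` (after sorting by start)
#' @return an object of class `gene_model`
#' @export
gene_model <- function(gene_id, chrom, strand, exons, transcripts) {
  if (is.data.frame(exons)) {
    exons <- GenomicRanges::GRanges(chrom, IRanges::IRanges(exons$start, exons$end),
                                    strand = strand)
  }
  if (!methods::is(exons, "GRanges")) stop2("`exons` must be a GRanges or data.frame")
  if (length(exons) < 1L) stop2("gene '", gene_id, "' has no exons")
  if (any(BiocGenerics::start(exons) < 1L)) stop2("exon start < 1")
  o <- order(BiocGenerics::start(exons))
  exons <- exons[o]
  if (length(exons) > 1L) {
    prev_end <- BiocGenerics::end(exons)[-length(exons)]
    next_start <- BiocGenerics::start(exons)[-1L]
    if (any(next_start <= prev_end)) {
      stop2("gene '", gene_id, "': overlapping exons in the exon union")
    }
  }
  if (!(strand %in% c("+", "-", "*"))) stop2("invalid strand: ", strand)
  transcripts <- lapply(transcripts, as.integer)
  for (tx in names(transcripts)) {
    idx <- transcripts[[tx]]
    if (any(idx < 1L | idx > length(exons))) {
      stop2("transcript '", tx, "': exon index out of range")
    }
    if (any(diff(idx) <= 0L)) {
      stop2("transcript '", tx, "': exon indices must be strictly increasing")
    }
  }
  structure(
    list(gene_id = gene_id, chrom = chrom, strand = strand,
         exons = exons, transcripts = transcripts),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model '%s' (%s%s): %d exons, %d transcripts\n",
              x$gene_id, x$chrom, x$strand, length(x$exons),
              length(x$transcripts)))
  cat("  span:", format_region(x$chrom, min(BiocGenerics::start(x$exons)),
                               max(BiocGenerics::end(x$exons))), "\n")
  invisible(x)
}

#' Genomic span of a gene model
#' @param gene a [gene_model()]
#' @return a length-1 GRanges covering all exons
#' @export
gene_span <- function(gene) {
  range(gene$exons, ignore.strand = TRUE)
}

#' Intron intervals of a gene model
#'
#' Gaps between consecutive exons of the exon union, 1-based inclusive.
#'
#' @param gene a [gene_model()]
#' @return GRanges of introns (empty for single-exon genes)
#' @export
gene_introns <- function(gene) {
  GenomicRanges::setdiff(gene_span(gene), gene$exons, ignore.strand = TRUE)
}

#' Read gene annotation from GTF
#'
#' Parses a GTF file (Ensembl-dialect attributes, `gene_id` and
#' `transcript_id`) into one [gene_model()] per gene. GTF's 1-based inclusive
#' coordinates are kept as-is (the package-internal convention). Exons are
#' grouped per transcript per gene and ordered by start; a transcript whose
#' exons overlap each other is rejected.
#'
#' @param path path to a GTF file
#' @return named list of `gene_model` objects (possibly empty)
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) stop2("annotation file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  body <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  if (length(body) == 0L) return(structure(list(), names = character(0)))
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf < 9L)) {
    stop2("malformed GTF line ", body[which(nf < 9L)[1L]], " in ", path,
          ": expected >= 9 tab-separated fields, got ", nf[which(nf < 9L)[1L]])
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[tolower(as.character(gr$type)) == "exon"]
  if (length(gr) == 0L) return(structure(list(), names = character(0)))
  if (is.null(gr$gene_id) || anyNA(gr$gene_id)) {
    stop2("GTF exon records missing gene_id attribute")
  }
  if (is.null(gr$transcript_id) || anyNA(gr$transcript_id)) {
    stop2("GTF exon records missing transcript_id attribute")
  }
  out <- list()
  for (gid in unique(gr$gene_id)) {
    g <- gr[gr$gene_id == gid]
    chrom <- as.character(GenomeInfoDb::seqnames(g))[1L]
    strand <- as.character(BiocGenerics::strand(g))[1L]
    # per-transcript overlap validation before collapsing to the exon union
    for (tid in unique(g$transcript_id)) {
      tg <- sort(GenomicRanges::granges(g[g$transcript_id == tid]), ignore.strand = TRUE)
      if (length(tg) > 1L &&
          any(BiocGenerics::start(tg)[-1L] <= BiocGenerics::end(tg)[-length(tg)])) {
        stop2("transcript '", tid, "' has overlapping exons")
      }
    }
    exon_union <- sort(unique(GenomicRanges::granges(g)), ignore.strand = TRUE)
    txs <- lapply(split(g, g$transcript_id), function(tg) {
      sort(S4Vectors::match(sort(GenomicRanges::granges(tg), ignore.strand = TRUE),
                            exon_union))
    })
    out[[gid]] <- gene_model(gid, chrom, strand, exon_union, txs)
  }
  out[order(names(out))]
}

#' Export a gene model back to GTF
#'
#' Inverse of [read_gene_annotation()]; coordinates round-trip bit-exactly.
#'
#' @param gene a [gene_model()]
#' @param path output GTF path
#' @param source source column value
#' @return `path`, invisibly
#' @export
write_gene_annotation <- function(gene, path, source = "exonscout") {
  recs <- list()
  for (tx in names(gene$transcripts)) {
    ex <- gene$exons[gene$transcripts[[tx]]]
    S4Vectors::mcols(ex) <- S4Vectors::DataFrame(
      source = source, type = "exon",
      gene_id = gene$gene_id, transcript_id = tx
    )
    recs[[tx]] <- ex
  }
  gr <- unlist(methods::as(recs, "GRangesList"), use.names = FALSE)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Spliced read alignments
#'
#' Thin wrapper around a [GenomicAlignments::GAlignments] object carrying the
#' aligned-block structure (M/=/X/D consume reference; N opens a new block;
#' I/S/H consume none) plus bookkeeping about filtered records.
#'
#' @keywords internal
new_spliced_reads <- function(aln, n_skipped_unmapped = 0L, n_dropped_filter = 0L) {
  structure(
    list(alignments = aln,
         n_reads = length(aln),
         n_skipped_unmapped = as.integer(n_skipped_unmapped),
         n_dropped_filter = as.integer(n_dropped_filter)),
    class = "spliced_reads"
  )
}

#' @export
print.spliced_reads <- function(x, ...) {
  cat(sprintf("spliced_reads: %d reads (%d unmapped/CIGAR-less skipped, %d dropped by uniqueness filter)\n",
              x$n_reads, x$n_skipped_unmapped, x$n_dropped_filter))
  invisible(x)
}

#' Aligned blocks of spliced reads
#'
#' One GRanges per read; gaps between consecutive blocks are splice skips
#' (CIGAR N operations).
#'
#' @param reads a `spliced_reads` object
#' @return a [GenomicRanges::GRangesList]
#' @export
read_blocks <- function(reads) {
  stopifnot(inherits(reads, "spliced_reads"))
  bl <- GenomicAlignments::grglist(reads$alignments, drop.D.ranges = FALSE)
  flat <- unlist(bl, use.names = FALSE)
  w <- BiocGenerics::width(flat)
  if (any(w == 0L)) {
    # degenerate CIGARs (insertions between two skips) yield zero-width
    # ranges; a block must consume reference
    idx <- rep(seq_along(bl), lengths(bl))
    bl <- GenomicRanges::split(flat[w > 0L],
                               factor(idx[w > 0L], levels = seq_along(bl)))
    names(bl) <- NULL
  }
  bl
}

#' Read spliced alignments from SAM
#'
#' Converts a headered SAM file to BAM on the fly (Rsamtools) and loads the
#' mapped records as a `spliced_reads` object. "Uniquely mapped" is defined as
#' mapping quality >= `min_mapq` and neither the secondary nor the
#' supplementary flag set; records failing the criterion are dropped when
#' `unique_only = TRUE`. Unmapped records (no CIGAR) are skipped and counted.
#'
#' @param path path to a SAM file (with header)
#' @param unique_only drop non-uniquely-mapped reads (default TRUE)
#' @param min_mapq mapping-quality threshold for uniqueness (default 30)
#' @return a `spliced_reads` object; the total record count and filter
#'   tallies are in fields `n_reads`, `n_skipped_unmapped`, `n_dropped_filter`
#' @export
read_alignments <- function(path, unique_only = TRUE, min_mapq = 30L) {
  if (!file.exists(path)) stop2("alignment file not found: ", path)
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam), add = TRUE)
  param_all <- Rsamtools::ScanBamParam(what = c("qname", "flag", "mapq"))
  aln <- GenomicAlignments::readGAlignments(bam, param = param_all)
  n_total <- Rsamtools::countBam(bam)$records
  n_unmapped <- n_total - length(aln)
  n_dropped <- 0L
  if (unique_only) {
    flag <- S4Vectors::mcols(aln)$flag
    mapq <- S4Vectors::mcols(aln)$mapq
    secondary <- bitwAnd(flag, 256L) != 0L
    supplementary <- bitwAnd(flag, 2048L) != 0L
    keep <- !secondary & !supplementary & !is.na(mapq) & mapq >= min_mapq
    n_dropped <- sum(!keep)
    aln <- aln[keep]
  }
  if (n_unmapped > 0L) {
    warning(n_unmapped, " unmapped/CIGAR-less record(s) skipped in ", path,
            call. = FALSE)
  }
  new_spliced_reads(aln, n_unmapped, n_dropped)
}

#' Construct spliced reads in memory
#'
#' Used by the simulator and by tests to bypass file I/O: builds the same
#' `spliced_reads` container from positions and CIGAR strings.
#'
#' @param chrom chromosome name (recycled)
#' @param pos 1-based leftmost mapped positions
#' @param cigar CIGAR strings
#' @param qname read names (default generated)
#' @param seqlengths optional named vector of chromosome lengths
#' @return a `spliced_reads` object
#' @export
spliced_reads <- function(chrom, pos, cigar, qname = NULL, seqlengths = NULL) {
  n <- length(pos)
  qname <- qname %||% sprintf("read%06d", seq_len(n))
  aln <- GenomicAlignments::GAlignments(
    seqnames = S4Vectors::Rle(rep_len(chrom, n)),
    pos = as.integer(pos), cigar = as.character(cigar),
    strand = S4Vectors::Rle(BiocGenerics::strand(rep("+", n)))
  )
  if (!is.null(seqlengths)) {
    GenomeInfoDb::seqlengths(aln) <- seqlengths[GenomeInfoDb::seqlevels(aln)]
  }
  S4Vectors::mcols(aln)$qname <- qname
  S4Vectors::mcols(aln)$flag <- rep(0L, n)
  S4Vectors::mcols(aln)$mapq <- rep(60L, n)
  new_spliced_reads(aln)
}

#' Read a scored BED track
#'
#' BED3/BED5 reader for methylation-style tracks. BED's 0-based half-open
#' coordinates are converted to the internal 1-based inclusive convention by
#' rtracklayer. A missing score column defaults to `default_score` and the
#' affected intervals are flagged in the `score_missing` metadata column;
#' methylation analyses refuse tracks whose missing scores were not
#' explicitly defaulted.
#'
#' @param path path to a BED file
#' @param default_score value used for scoreless records (default 0)
#' @return a GRanges sorted by start with metadata columns `score` and
#'   `score_missing`
#' @export
read_scored_bed <- function(path, default_score = 0) {
  if (!file.exists(path)) stop2("BED file not found: ", path)
  gr <- rtracklayer::import(path, format = "bed")
  if (any(BiocGenerics::width(gr) < 1L)) stop2("BED record with start >= end in ", path)
  missing <- if (is.null(gr$score)) rep(TRUE, length(gr)) else is.na(gr$score)
  score <- if (is.null(gr$score)) rep(default_score, length(gr)) else gr$score
  score[missing] <- default_score
  out <- GenomicRanges::granges(gr)
  S4Vectors::mcols(out)$score <- as.numeric(score)
  S4Vectors::mcols(out)$score_missing <- missing
  sort(out, ignore.strand = TRUE)
}

#' Write a scored track as BED
#'
#' @param gr GRanges with a numeric `score` column (optional)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_scored_bed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Serialize a phylogenetic tree as Newick
#'
#' Standard Newick with branch lengths, `;`-terminated; round-trips through
#' [ape::read.tree()] to an isomorphic tree. A single taxon (no tree
#' structure) may be given as a bare character label and serializes as
#' `"label;"`.
#'
#' @param tree an [ape] `phylo` object (e.g. from [build_nj_tree()]), or a
#'   single character label
#' @param path optional output file
#' @return the Newick string, invisibly if `path` is given
#' @export
write_newick <- function(tree, path = NULL) {
  if (is.character(tree) && length(tree) == 1L) {
    txt <- paste0(tree, ";")
  } else {
    if (!inherits(tree, "phylo")) stop2("`tree` must be a phylo object or a single label")
    txt <- ape::write.tree(tree)
  }
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
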